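params_fixed <- function(...) {
  segmentation_params(threshold_method = "fixed", fixed_threshold = 50,
                      min_cell_area = 0, border_policy = "keep", ...)
}

test_that("disjoint bright blobs are labeled with their exact areas", {
  img <- matrix(0, 60, 60)
  img <- draw_disc(img, 15, 15, 6, 100)
  img <- draw_disc(img, 45, 45, 4, 100)
  lm <- segment_cells(img, params_fixed())
  ids <- setdiff(unique(as.vector(lm$labels)), 0L)
  expect_length(ids, 2)
  areas <- sort(tabulate(lm$labels[lm$labels != 0]))
  expect_equal(areas, sort(c(sum(draw_disc(matrix(0, 60, 60), 15, 15, 6) != 0),
                             sum(draw_disc(matrix(0, 60, 60), 45, 45, 4) != 0))))
})

test_that("watershed splits two overlapping discs into two labels", {
  img <- matrix(0, 60, 60)
  img <- draw_disc(img, 30, 22, 10, 100)
  img <- draw_disc(img, 30, 40, 10, 100)  # overlap, two distance maxima
  lm <- segment_cells(img, params_fixed())
  expect_length(setdiff(unique(as.vector(lm$labels)), 0L), 2)
})

test_that("objects below the minimum area are removed", {
  img <- matrix(0, 40, 40)
  img <- draw_disc(img, 20, 20, 3, 100)  # area ~29 px
  lm <- segment_cells(img, segmentation_params(threshold_method = "fixed",
                                               fixed_threshold = 50,
                                               min_cell_area = 100))
  expect_equal(sum(lm$labels), 0)
})

test_that("degenerate inputs behave as specified", {
  expect_equal(sum(segment_cells(matrix(0, 30, 30), params_fixed())$labels), 0)
  expect_error(segment_cells(matrix(5, 30, 30),
                             segmentation_params(threshold_method = "otsu")),
               "degenerate")
  expect_error(segment_cells(matrix(c(NA, 1:8), 3, 3), params_fixed()),
               "finite")
})

test_that("border objects are dropped under the default policy", {
  img <- matrix(0, 40, 40)
  img[1:6, 10:20] <- 100         # touches the top border
  img <- draw_disc(img, 25, 25, 5, 100)
  lm <- segment_cells(img, segmentation_params(threshold_method = "fixed",
                                               fixed_threshold = 50,
                                               min_cell_area = 0,
                                               border_policy = "drop"))
  expect_length(setdiff(unique(as.vector(lm$labels)), 0L), 1)
})

test_that("watershed equals connected components when nothing touches", {
  set.seed(42)
  img <- matrix(0, 120, 120)
  centers <- cbind(c(20, 20, 60, 95, 95), c(20, 95, 58, 25, 95))
  for (i in seq_len(nrow(centers)))
    img <- draw_disc(img, centers[i, 1], centers[i, 2], sample(4:8, 1), 100)
  ws <- segment_cells(img, params_fixed())
  cc <- label_components(img > 50, connectivity = 8)
  expect_true(same_partition(ws$labels, cc))
})

test_that("connectivity 4 and 8 differ on diagonal contacts", {
  m <- matrix(0, 10, 10)
  m[3, 3] <- 1; m[4, 4] <- 1
  expect_length(setdiff(unique(as.vector(label_components(m, 4))), 0L), 2)
  expect_length(setdiff(unique(as.vector(label_components(m, 8))), 0L), 1)
})

test_that("curation removes dead and merged objects with logged reasons", {
  lab <- matrix(0L, 80, 80)
  lab[draw_disc(matrix(0, 80, 80), 20, 20, 8) != 0] <- 1L
  lab[draw_disc(matrix(0, 80, 80), 20, 60, 8) != 0] <- 2L
  # object 3: a plus-shape (two crossing bars), far from convex
  lab[35:70, 48:53] <- 3L
  lab[50:55, 35:70] <- 3L
  chl <- matrix(0, 80, 80)
  chl[lab == 1] <- 500; chl[lab == 3] <- 500  # object 2 stays dark -> dead
  cur <- curate_cells(lab, chl, frame_index = 1L)
  expect_setequal(cur$log$reason, c("dead", "overlap"))
  expect_equal(cur$log$label[cur$log$reason == "dead"], 2L)
  expect_equal(cur$log$label[cur$log$reason == "overlap"], 3L)
  expect_setequal(setdiff(unique(as.vector(cur$labels$labels)), 0L), 1L)
})

test_that("curation is the identity on an all-healthy frame", {
  lab <- matrix(0L, 60, 60)
  lab[draw_disc(matrix(0, 60, 60), 20, 20, 7) != 0] <- 1L
  lab[draw_disc(matrix(0, 60, 60), 40, 40, 7) != 0] <- 2L
  chl <- matrix(0, 60, 60); chl[lab != 0] <- 400
  cur <- curate_cells(lab, chl)
  expect_equal(nrow(cur$log), 0)
  expect_identical(cur$labels$labels, lab)
})

test_that("puncta size filter excludes strictly-smaller-than-62 only", {
  cells <- matrix(1L, 120, 60)
  gfp <- matrix(0, 120, 60)
  b30 <- serpentine_blob(30, 10, 10, 8)
  b62 <- serpentine_blob(62, 40, 10, 10)
  b100 <- serpentine_blob(100, 80, 10, 12)
  for (b in list(b30, b62, b100)) gfp[b] <- 100
  pm <- segment_puncta(gfp, cells,
                       segmentation_params(puncta_threshold_method = "fixed",
                                           puncta_fixed_threshold = 50),
                       size_filter = TRUE)
  parents <- attr(pm, "parents")
  expect_setequal(parents$area_px, c(62, 100))  # 62 is retained, 30 is not
  expect_equal(attr(pm, "n_size_filtered"), 1L)
  # with the filter off for a non-filtered strain class, all three survive
  pm_off <- segment_puncta(gfp, cells,
                           segmentation_params(puncta_threshold_method = "fixed",
                                               puncta_fixed_threshold = 50),
                           size_filter = FALSE)
  expect_setequal(attr(pm_off, "parents")$area_px, c(30, 62, 100))
})

test_that("puncta outside any cell are not emitted and pixels stay in cells", {
  cells <- matrix(0L, 60, 60)
  cells[draw_disc(matrix(0, 60, 60), 20, 20, 12) != 0] <- 1L
  gfp <- matrix(0, 60, 60)
  gfp <- draw_disc(gfp, 20, 20, 4, 100)   # inside cell 1
  gfp <- draw_disc(gfp, 48, 48, 4, 100)   # on background
  pm <- segment_puncta(gfp, cells,
                       segmentation_params(puncta_threshold_method = "fixed",
                                           puncta_fixed_threshold = 50),
                       size_filter = FALSE)
  parents <- attr(pm, "parents")
  expect_equal(nrow(parents), 1)
  expect_equal(parents$parent_cell, 1L)
  expect_true(all(cells[pm$labels != 0] != 0))  # puncta pixels within cells
})

test_that("parent assignment: centroid rule, majority fallback, tie break", {
  # centroid rule: punctum straddles two adjacent cells, centroid in cell 2
  cells <- matrix(0L, 40, 40)
  cells[, 1:20] <- 1L; cells[, 21:40] <- 2L
  gfp <- matrix(0, 40, 40)
  gfp[18:22, 17:26] <- 100   # 4 columns in cell 1, 6 in cell 2
  pm <- segment_puncta(gfp, cells,
                       segmentation_params(puncta_threshold_method = "fixed",
                                           puncta_fixed_threshold = 50),
                       size_filter = FALSE)
  p <- attr(pm, "parents")
  expect_equal(p$parent_cell, 2L)
  expect_equal(p$assigned_by, "centroid")

  # majority fallback: ring-shaped punctum in an annular cell; the centroid
  # lands in a different cell at the ring center
  ann <- function(cy, cx, r0, r1) {
    m <- matrix(FALSE, 41, 41)
    for (i in 1:41) for (j in 1:41) {
      d2 <- (i - cy)^2 + (j - cx)^2
      if (d2 >= r0^2 && d2 <= r1^2) m[i, j] <- TRUE
    }
    m
  }
  cells2 <- matrix(0L, 41, 41)
  cells2[ann(21, 21, 8, 15)] <- 1L          # annular cell
  cells2[ann(21, 21, 0, 5)] <- 2L           # disc at the ring center
  gfp2 <- matrix(0, 41, 41)
  gfp2[ann(21, 21, 9, 13)] <- 100           # ring punctum inside cell 1
  pm2 <- segment_puncta(gfp2, cells2,
                        segmentation_params(puncta_threshold_method = "fixed",
                                            puncta_fixed_threshold = 50),
                        size_filter = FALSE)
  p2 <- attr(pm2, "parents")
  expect_equal(p2$parent_cell, 1L)
  expect_equal(p2$assigned_by, "majority")

  # exact overlap tie: symmetric ring over two half-plane cells, centroid in
  # a third cell; the lower label id wins
  ann5 <- function(cy, cx, r0, r1, n = 42) {
    m <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      d2 <- (i - cy)^2 + (j - cx)^2
      if (d2 >= r0^2 && d2 <= r1^2) m[i, j] <- TRUE
    }
    m
  }
  cells3 <- matrix(0L, 42, 42)
  cells3[, 1:21] <- 1L; cells3[, 22:42] <- 2L
  ring <- ann5(21.5, 21.5, 9, 13)
  center <- ann5(21.5, 21.5, 0, 5)
  cells3[center] <- 3L
  gfp3 <- matrix(0, 42, 42); gfp3[ring] <- 100
  pm3 <- segment_puncta(gfp3, cells3,
                        segmentation_params(puncta_threshold_method = "fixed",
                                            puncta_fixed_threshold = 50),
                        size_filter = FALSE)
  p3 <- attr(pm3, "parents")
  expect_equal(p3$parent_cell, 1L)
  expect_equal(p3$assigned_by, "majority_tie")
})
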