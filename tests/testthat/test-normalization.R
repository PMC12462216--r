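make_meta <- function(counts, nuclei = 200L, group = "HC") {
  data.frame(roi_id = colnames(counts),
             subject_id = "S1",
             group = rep_len(group, ncol(counts)),
             quadrant = "DM",
             slide_id = "S1",
             nuclei_count = rep_len(nuclei, ncol(counts)),
             stringsAsFactors = FALSE)
}

test_that("the nuclei filter keeps ROIs strictly exceeding the threshold", {
  m <- matrix(1:9, 3, 3, dimnames = list(paste0("G", 1:3), paste0("R", 1:3)))
  meta <- make_meta(m, nuclei = c(50L, 91L, 200L))
  flt <- filter_rois(m, meta, min_nuclei = 90)
  expect_equal(colnames(flt$counts), c("R2", "R3"))
  expect_equal(flt$meta$roi_id, c("R2", "R3"))
  expect_equal(nrow(flt$counts), 3L)  # genes untouched

  # all above threshold: identity; all below: error
  expect_identical(filter_rois(m, make_meta(m, 300L))$counts, m)
  expect_error(filter_rois(m, make_meta(m, 10L)), "all ROIs")
})

test_that("upper-quartile normalization equalizes quartiles and is idempotent", {
  set.seed(1)
  m <- matrix(rnbinom(600, mu = 40, size = 2), 100, 6,
              dimnames = list(paste0("G", 1:100), paste0("R", 1:6)))
  norm <- between_lane_normalize(m, "upper")
  uq <- apply(norm$values, 2, function(x) quantile(x[x > 0], 0.75))
  expect_lt(diff(range(uq)) / mean(uq), 1e-9)

  # idempotent: renormalizing the normalized values changes nothing
  v <- norm$values
  norm2 <- between_lane_normalize(v, "upper")
  expect_equal(norm2$values, v, tolerance = 1e-9)

  # scaling algebra: column2 = 2 * column1 becomes identical columns
  m2 <- cbind(R1 = m[, 1], R2 = 2L * m[, 1])
  n2 <- between_lane_normalize(m2, "upper")
  expect_equal(n2$values[, 1], n2$values[, 2], ignore_attr = TRUE)

  # identical columns are only rescaled by 1
  m3 <- cbind(R1 = m[, 1], R2 = m[, 1])
  n3 <- between_lane_normalize(m3, "upper")
  expect_equal(unname(n3$scale_factors), c(1, 1))

  zero_col <- cbind(R1 = m[, 1], R2 = rep(0L, 100))
  expect_error(between_lane_normalize(zero_col, "upper"), "R2")
})

test_that("full-quantile normalization equalizes the column distributions", {
  set.seed(2)
  # continuous-ish counts avoid ties so sorted multisets match exactly
  m <- matrix(sample.int(100000, 300), 50, 6,
              dimnames = list(paste0("G", 1:50), paste0("R", 1:6)))
  norm <- between_lane_normalize(m, "full")
  sorted <- apply(norm$values, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  # ranks are preserved within each column
  for (j in 1:6) expect_equal(order(norm$values[, j]), order(m[, j]))
})

test_that("empirical controls avoid planted DE genes and follow the rank rule", {
  hits <- 0L
  n_seeds <- 20L
  for (i in seq_len(n_seeds)) {
    sim <- tiny_two_group(n_genes = 300, n_per = 8, seed = 400 + i,
                          frac_de = 0.1, dispersion = 0.1)
    controls <- select_empirical_controls(sim$counts, sim$meta,
                                          n_controls = 30)
    if (length(intersect(controls, sim$truth$de_genes$gene)) == 0L) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.95)

  sim <- tiny_two_group(n_genes = 50, n_per = 6, seed = 9)
  expect_identical(select_empirical_controls(sim$counts, sim$meta, 0),
                   character(0))
  expect_error(select_empirical_controls(sim$counts, sim$meta, 50),
               "smaller")
})

test_that("RUV factors recover a planted loading and vanish under the null", {
  cors <- vapply(1:5, function(i) {
    cfg <- simulation_config(n_genes = 800, n_control_genes = 80,
                             frac_de = 0.1, n_unwanted_factors = 1,
                             unwanted_sigma = 0.5, seed = 500 + i)
    sim <- generate_dataset(cfg)
    norm <- between_lane_normalize(sim$counts)
    ruv <- estimate_ruv_factors(norm, sim$truth$control_genes, k = 1)
    abs(cor(ruv[, 1], sim$truth$unwanted_loadings[, 1]))
  }, 0)
  expect_true(all(cors >= 0.9))

  # loadings are mean-centered; k = 0 gives an empty matrix
  cfg <- simulation_config(n_genes = 400, n_control_genes = 40, seed = 1)
  sim <- generate_dataset(cfg)
  norm <- between_lane_normalize(sim$counts)
  ruv <- estimate_ruv_factors(norm, sim$truth$control_genes, k = 2)
  expect_equal(colMeans(ruv), c(W1 = 0, W2 = 0), tolerance = 1e-12)
  expect_equal(ncol(estimate_ruv_factors(norm, sim$truth$control_genes, 0)), 0)
  expect_error(estimate_ruv_factors(norm, sim$truth$control_genes, k = 500),
               "feasible rank")

  # constant controls carry no variation
  flat <- matrix(5, 20, 6, dimnames = list(paste0("G", 1:20), paste0("R", 1:6)))
  expect_equal(max(abs(estimate_ruv_factors(flat, paste0("G", 1:20), 1))), 0)
})
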