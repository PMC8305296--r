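# Retention indices, peak-table operations, NIPALS PLS-DA and VID selection.

test_that("retention index interpolates linearly on the alkane ladder", {
  expect_equal(retention_index(20.0, c(14, 15), c(20.0, 22.0)), 1400)
  expect_equal(retention_index(21.5, c(14, 15), c(20.0, 22.0)), 1475)
  ladder <- seq(2, 30, by = 2)
  expect_equal(retention_index(mean(ladder[3:4]), 8:22, ladder), 1050)
  expect_error(retention_index(1.0, 8:22, ladder), "outside")
  expect_equal(retention_index(1.0, 8:22, ladder, extrapolate = TRUE),
               800 - 100 / 2)
})

test_that("internal-standard normalisation divides rows and drops the IS", {
  areas <- matrix(c(2, 4, 8,
                    3, 6, 12,
                    10, 20, 40), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("s", 1:3), c("v1", "v2", "is")))
  pt <- peak_table(areas, class = c("a", "a", "b"), internal_standard = "is")
  norm <- normalize_peaks(pt)
  expect_equal(unname(norm$areas[, "v1"]), c(0.25, 0.25, 0.25))
  expect_equal(unname(norm$areas[, "v2"]), c(0.5, 0.5, 0.5))
  expect_false("is" %in% colnames(norm$areas))
  # doubling a sample's raw areas together with its IS changes nothing
  areas2 <- areas; areas2[1, ] <- 2 * areas2[1, ]
  pt2 <- peak_table(areas2, class = c("a", "a", "b"),
                    internal_standard = "is")
  expect_equal(normalize_peaks(pt2)$areas, norm$areas)
  areas3 <- areas; areas3[2, "is"] <- 0
  expect_error(normalize_peaks(peak_table(areas3, class = c("a", "a", "b"),
                                          internal_standard = "is")),
               "positive")
})

test_that("total peak area sums rows and is order-invariant", {
  pt <- sim_peak_table(seed = 12)
  tot <- total_peak_area(pt)
  expect_equal(unname(tot), unname(rowSums(pt$areas)))
  shuf <- peak_table(pt$areas[, sample(ncol(pt$areas))], class = pt$class)
  expect_equal(unname(total_peak_area(shuf)), unname(tot))
  single <- peak_table(pt$areas[, 1, drop = FALSE], class = pt$class)
  expect_equal(unname(total_peak_area(single)), unname(pt$areas[, 1]))
})

test_that("globally attenuated class is flagged lower in total area", {
  pt <- sim_peak_table(discriminant = rep(list(integer()), 4), seed = 13)
  areas <- pt$areas
  areas[pt$class == "FD", ] <- areas[pt$class == "FD", ] * 0.3
  cmp <- total_peak_area(peak_table(areas, pt$class), compare = TRUE)$comparison
  tab <- cmp$table
  fd <- tab[tab$group == "FD", ]
  others <- tab[tab$group != "FD", ]
  expect_true(all(fd$mean < others$mean))
  expect_false(fd$letters %in% others$letters)
})

test_that("a single strong variable separates two classes on LV1", {
  set.seed(41)
  n <- 16
  x <- cbind(sep = rep(c(0, 5), each = n / 2) + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 4), n))
  fit <- plsda(x, rep(c("a", "b"), each = n / 2), ncomp = 2)
  s1 <- fit$T[1:(n / 2), 1]; s2 <- fit$T[(n / 2 + 1):n, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))
  expect_identical(fit$T,
                   plsda(x, rep(c("a", "b"), each = n / 2), ncomp = 2)$T)
})

test_that("first PLS weight equals the dominant singular vector of X'Y", {
  pt <- sim_peak_table(seed = 14)
  fit <- plsda(pt, ncomp = 2)
  # closed-form oracle: w1 is the leading left singular vector of X0' Y0
  sv <- svd(crossprod(fit$X0, fit$Y0))
  expect_equal(abs(sum(fit$W[, 1] * sv$u[, 1])), 1, tolerance = 1e-6)
})

test_that("permuted labels give near-chance cross-validated accuracy", {
  pt <- sim_peak_table(effect_size = 3, seed = 15)
  set.seed(16)
  perm <- sample(as.character(pt$class))
  acc <- plsda_ncomp(pt$areas, perm, max_ncomp = 3)$accuracy
  # chance is 0.25 for four balanced classes; binomial 99% bound at n = 24
  expect_lt(max(acc), 0.25 + 2.6 * sqrt(0.25 * 0.75 / 24))
  real <- plsda_ncomp(pt, max_ncomp = 3)
  expect_gt(max(real$accuracy), 0.9)
})

test_that("explained Y variance per LV is non-increasing", {
  pt <- sim_peak_table(effect_size = 3, seed = 17)
  fit <- plsda(pt, ncomp = 3)
  expect_true(all(diff(fit$R2Y) <= 1e-10))
  expect_true(all(fit$R2X >= 0 & fit$R2X <= 1))
})

test_that("constant variables are dropped with a warning", {
  pt <- sim_peak_table(seed = 18)
  areas <- pt$areas; areas[, 3] <- 7
  expect_warning(fit <- plsda(peak_table(areas, pt$class), ncomp = 2),
                 "constant")
  expect_equal(nrow(fit$W), ncol(areas) - 1L)
})

test_that("VID is signed and extreme for (anti-)indicator variables", {
  set.seed(51)
  n <- 12
  cls <- rep(c("a", "b"), each = n / 2)
  ind <- as.numeric(cls == "a")
  x <- cbind(ind = ind, anti = -ind, matrix(rnorm(n * 6), n))
  fit <- plsda(x, cls, ncomp = 2)
  v <- vid_coefficients(fit)
  # reconstruction-based VID approaches +/-1 up to the rank-2 model error
  expect_equal(v["ind", "a"], 1, tolerance = 0.01)
  expect_equal(v["anti", "a"], -1, tolerance = 0.01)
  expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
})

test_that("VID is invariant to affine rescaling of a raw variable", {
  pt <- sim_peak_table(seed = 19)
  v1 <- vid_coefficients(plsda(pt, ncomp = 3))
  areas <- pt$areas
  areas[, 5] <- areas[, 5] * 3 + 100       # affine map on one variable
  v2 <- vid_coefficients(plsda(peak_table(areas, pt$class), ncomp = 3))
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("discriminant selection applies the threshold rule and ordering", {
  vid <- matrix(c(0.95, 0.81, 0.79, -0.9), 4, 1,
                dimnames = list(paste0("v", 1:4), "cls"))
  class(vid) <- c("vid_table", class(vid))
  out <- select_discriminants(vid, 0.8)
  expect_equal(out$variable, c("v1", "v2", "v4"))
  expect_equal(out$VID, c(0.95, 0.81, -0.9))
  expect_equal(nrow(select_discriminants(vid, 1.0)), 0)
  low <- vid * 0.5
  expect_equal(nrow(select_discriminants(low, 0.8)), 0)
})

test_that("planted discriminants are recovered at a strong effect", {
  pt <- sim_peak_table(effect_size = 5, seed = 20)
  disc <- select_discriminants(vid_coefficients(plsda(pt, ncomp = 3)), 0.8)
  planted <- attr(pt, "discriminant")
  for (cl in names(planted)) {
    want <- colnames(pt$areas)[planted[[cl]]]
    expect_true(all(want %in% disc$variable[disc$class == cl]), label = cl)
  }
})

test_that("bi-plot coordinates respect the correlation geometry", {
  pt <- sim_peak_table(effect_size = 5, seed = 21)
  areas <- rbind(pt$areas, pt$areas[1, ])     # duplicate one sample
  fit <- plsda(peak_table(areas, c(as.character(pt$class),
                                   as.character(pt$class[1]))), ncomp = 3)
  bc <- biplot_coordinates(fit)
  n <- nrow(pt$areas)
  expect_equal(bc$scores[n + 1, ], bc$scores[1, ])
  expect_true(all(sqrt(rowSums(bc$variables^2)) <= 1 + 1e-9))
  expect_equal(unname(bc$circle_radii), c(0.7, 1))
  expect_error(biplot_coordinates(fit, lv = c(1, 9)), "beyond")
})

test_that("two-class bi-plot places planted variables at the rim", {
  # with two classes the first LV pair carries the whole class contrast,
  # so planted variables approach the unit circle and noise stays inside
  pt <- sim_peak_table(n_classes = 2, classes = c("a", "b"),
                       discriminant = list(1:2, 3:4), effect_size = 5,
                       seed = 22)
  bc <- biplot_coordinates(plsda(pt, ncomp = 2))
  r <- sqrt(rowSums(bc$variables^2))
  planted_idx <- 1:4
  expect_gt(min(r[planted_idx]), 0.75)
  expect_lt(median(r[-planted_idx]), min(r[planted_idx]))
})
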