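make_means <- function(M) {
  structure(M, traits = trait_spec_list_public(colnames(M)),
            class = c("genotype_means", "matrix"))
}

test_that("rescaling maps ranges onto a directed 0-100 scale", {
  M <- cbind(up = c(5, 10, 15), down = c(5, 10, 15))
  rownames(M) <- c("a", "b", "c")
  specs <- c(trait_spec_list_public("up", sense = "increase"),
             trait_spec_list_public("down", sense = "decrease"))
  rx <- rescale_traits(M, specs)
  expect_equal(unname(rx[, "up"]), c(0, 50, 100))
  expect_equal(unname(rx[, "down"]), c(100, 50, 0))
  # monotone: rankings preserved (reversed for decrease-sense)
  expect_equal(order(rx[, "up"]), order(M[, "up"]))
  expect_equal(order(rx[, "down"]), rev(order(M[, "down"])))
  M0 <- cbind(up = c(1, 1, 1), down = 1:3)
  expect_error(rescale_traits(M0, specs), "up")
})

test_that("rescaling preserves the correlation structure up to sense flips", {
  set.seed(1)
  M <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("g", 1:10), paste0("t", 1:4)))
  specs <- c(trait_spec_list_public(c("t1", "t2", "t3")),
             trait_spec_list_public("t4", sense = "decrease"))
  rx <- rescale_traits(M, specs)
  flip <- diag(c(1, 1, 1, -1))
  expect_equal(cor(unclass(rx)), flip %*% cor(M) %*% flip,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("disjoint perfectly correlated trait pairs form two unit-communality factors", {
  set.seed(2)
  u <- rnorm(12)
  v <- residuals(lm(rnorm(12) ~ u)) # exactly uncorrelated with u
  M <- cbind(a1 = u, a2 = 2 * u + 3, b1 = v, b2 = -v + 1)
  rownames(M) <- paste0("g", 1:12)
  fm <- suppressWarnings(fit_factor_model(make_means(M) |> rescale_traits()))
  expect_equal(fm$m, 2)
  expect_equal(unname(fm$communality), rep(1, 4), tolerance = 1e-6)
  # each trait assigned to the factor of its own block
  expect_equal(fm$assignment[["a1"]], fm$assignment[["a2"]])
  expect_equal(fm$assignment[["b1"]], fm$assignment[["b2"]])
  expect_false(fm$assignment[["a1"]] == fm$assignment[["b1"]])
})

test_that("varimax rotation preserves communality and fixes simple structures", {
  trial <- simulate_trial(demo_trial_config(seed = 5))
  rx <- rescale_traits(genotype_means(trial))
  fm <- fit_factor_model(rx)
  # recompute unrotated communality independently from the eigendecomposition
  R <- cor(unclass(rx))
  e <- eigen(R, symmetric = TRUE)
  A <- e$vectors[, 1:fm$m] %*% diag(sqrt(e$values[1:fm$m]))
  expect_equal(unname(fm$communality), unname(rowSums(A^2)), tolerance = 1e-9)
  # a loading matrix already in simple structure is a varimax fixed point
  L <- rbind(c(0.9, 0), c(0.85, 0), c(0, 0.8), c(0, 0.95))
  rot <- varimax(L, normalize = TRUE)
  expect_equal(abs(unclass(rot$loadings)), abs(L), tolerance = 1e-6)
})

test_that("a genotype best in every trait sits at the ideotype", {
  set.seed(3)
  M <- matrix(rnorm(10 * 4, mean = 20), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("t", 1:4)))
  M[7, ] <- apply(M, 2, max) + 1
  rx <- rescale_traits(make_means(M))
  fm <- fit_factor_model(rx)
  ideo <- build_ideotype(rx, fm)
  expect_equal(unname(fm$scores["g7", ]), ideo, tolerance = 1e-9)
  idx <- mgidi_index(fm, ideo)
  expect_equal(unname(idx["g7"]), 0, tolerance = 1e-9)
  expect_equal(names(which.min(idx)), "g7")
})

test_that("the ideotype score is the linear image of the all-100 row", {
  trial <- simulate_trial(demo_trial_config(seed = 9))
  rx <- rescale_traits(genotype_means(trial))
  fm <- fit_factor_model(rx)
  ideo <- build_ideotype(rx, fm)
  z <- (rep(100, ncol(rx)) - colMeans(unclass(rx))) / apply(unclass(rx), 2, sd)
  ref <- as.numeric(z %*% solve(cor(unclass(rx))) %*% fm$loadings)
  expect_equal(ideo, ref, tolerance = 1e-9)
})

test_that("the index is a plain Euclidean distance in score space", {
  fake <- structure(list(
    m = 2L,
    scores = matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE,
                    dimnames = list(c("a", "b"), c("FA1", "FA2")))
  ), class = "factor_model")
  idx <- mgidi_index(fake, c(0, 0))
  expect_equal(unname(idx), c(5, 0))
  # brute-force equivalence on a random score matrix
  set.seed(4)
  S <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  fake2 <- structure(list(m = 3L, scores = S), class = "factor_model")
  ideo <- rnorm(3)
  brute <- sapply(1:5, function(i) sqrt(sum((S[i, ] - ideo)^2)))
  expect_equal(unname(mgidi_index(fake2, ideo)), brute)
  expect_error(mgidi_index(fake2, 1:2), "dimension")
})

test_that("selection takes round(alpha/100 * n) genotypes, at least one", {
  idx42 <- setNames(seq_len(42), sprintf("G%02d", 1:42))
  expect_length(select_genotypes(idx42, 15), 6)
  idx10 <- setNames(1:10, letters[1:10])
  expect_length(select_genotypes(idx10, 10), 1)
  expect_length(select_genotypes(idx10, 100), 10)
  expect_length(select_genotypes(idx10, 1), 1)
  # ties broken by genotype ID
  tied <- setNames(c(1, 1, 1, 2), c("d", "b", "a", "c"))
  expect_equal(select_genotypes(tied, 50), c("a", "b"))
})

test_that("selection gains follow the response equation and its edge cases", {
  M <- cbind(t1 = c(90, 100, 110, 120), t2 = c(10, 10, 10, 10))
  rownames(M) <- paste0("g", 1:4)
  gm <- make_means(M)
  sg <- suppressWarnings(selection_gains(gm, c("g3", "g4"), c(t1 = 0.8, t2 = 1)))
  # Xs = 115, Xo = 105 -> (10/105)*0.8*100
  expect_equal(sg$sg_pct[sg$trait == "t1"], 10 / 105 * 0.8 * 100)
  expect_equal(sg$sg_pct[sg$trait == "t2"], 0)
  M2 <- cbind(t = c(90, 110, 130))
  rownames(M2) <- paste0("g", 1:3)
  # selected mean equal to the population mean -> zero gain
  sg2 <- selection_gains(make_means(M2), "g2", c(t = 0.8))
  expect_equal(sg2$sg_pct, 0)
  # direct arithmetic: Xs 130, Xo 110, h2 0.8
  sg3 <- selection_gains(make_means(M2), "g3", c(t = 0.8))
  expect_equal(sg3$sg_pct, (130 - 110) / 110 * 0.8 * 100)
  # the worked response example: Xs 110, Xo 100, h2 0.8 -> 8%
  M3 <- cbind(t = c(90, 110))
  rownames(M3) <- c("g1", "g2")
  expect_equal(selection_gains(make_means(M3), "g2", c(t = 0.8))$sg_pct, 8)
  # selecting everyone gives zero gain
  sg_all <- selection_gains(gm, rownames(M), c(t1 = 0.9, t2 = 0.9))
  expect_true(all(sg_all$sg_pct == 0))
})

test_that("factor contributions split the squared distance and sum to one", {
  S <- matrix(c(1, 1, 1,
                2, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("eq", "one"), NULL))
  fake <- structure(list(m = 3L, scores = S), class = "factor_model")
  pr <- strengths_weaknesses(fake, c(0, 0, 0))
  expect_equal(unname(pr["eq", ]), rep(1 / 3, 3))
  expect_equal(unname(pr["one", ]), c(1, 0, 0))
  expect_equal(unname(rowSums(pr)), c(1, 1))
  # a genotype at the ideotype is reported uniform with a warning
  expect_warning(pr0 <- strengths_weaknesses(fake, c(1, 1, 1)), "ideotype")
  expect_equal(unname(pr0["eq", ]), rep(1 / 3, 3))
  expect_equal(attr(pr0, "undefined"), "eq")
})

test_that("the full mgidi fit is coherent and order-invariant", {
  trial <- simulate_trial(demo_trial_config(seed = 13))
  fit <- mgidi(trial, alpha = 15)
  expect_s3_class(fit, "mgidi")
  expect_length(fit$selected, 6)
  expect_true(all(fit$index >= 0))
  expect_equal(sum(fit$ranking$selected), 6)
  expect_equal(fit$ranking$genotype[1], fit$selected[1])
  expect_equal(unname(rowSums(fit$contributions)), rep(1, 6), tolerance = 1e-12)
  # order invariance: shuffle plot rows, refit
  set.seed(14)
  shuffled <- as.data.frame(trial)[sample(nrow(trial)), ]
  trial2 <- trial_table(shuffled, attr(trial, "traits"))
  fit2 <- mgidi(trial2, alpha = 15)
  expect_equal(fit2$index[names(fit$index)], fit$index, tolerance = 1e-9)
  expect_setequal(fit2$selected, fit$selected)
  # predict on the training means reproduces the fitted index
  pred <- predict(fit, unclass(fit$means))
  expect_equal(pred[names(fit$index)], fit$index, tolerance = 1e-9)
  # coef returns the rotated loadings
  expect_equal(coef(fit), fit$model$loadings)
})

test_that("mgidi accepts plain genotype means with supplied heritability", {
  set.seed(15)
  M <- matrix(rnorm(60, 50, 5), 15, 4,
              dimnames = list(sprintf("g%02d", 1:15), paste0("t", 1:4)))
  gm <- make_means(M)
  h2 <- setNames(rep(0.9, 4), colnames(M))
  fit <- mgidi(gm, alpha = 20, h2 = h2)
  expect_length(fit$selected, 3)
  expect_error(mgidi(gm, alpha = 20), "h2")
})
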