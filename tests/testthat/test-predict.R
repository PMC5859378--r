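# BLUP via Henderson's equations and cross-validated prediction.

test_that("MME solution matches the closed form for unrelated individuals", {
  set.seed(61)
  n <- 50
  y <- rnorm(n, 10, 2)
  X <- matrix(1, n, 1)
  ids <- sprintf("i%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  sg <- 1.2; se <- 2.4
  sol <- solve_mme(y, X, ids, K, sg, se)
  h2 <- sg / (sg + se)
  # with A = I and one record each: u_i = h2 * (y_i - b)
  expect_equal(unname(sol$u), h2 * (y - sol$b), tolerance = 1e-10)
})

test_that("MME solution matches a direct linear solve on the 3-individual toy", {
  # parent p with one record, offspring o1, o2 without; lambda = 2
  ped <- data.frame(id = c("p", "m", "o1", "o2"),
                    sire = c("0", "0", "p", "p"),
                    dam = c("0", "0", "m", "m"))
  A <- pedigree_amat(ped)[c("p", "o1", "o2"), c("p", "o1", "o2")]
  y <- 7; lambda <- 2
  sol <- solve_mme(y, matrix(1, 1, 1), "p", A, sigma_g2 = 1, sigma_e2 = 2)
  # oracle: build the 4x4 MME by hand and invert directly
  Z <- matrix(c(1, 0, 0), 1)
  Ainv <- solve(A)
  C <- rbind(cbind(1, Z), cbind(t(Z), t(Z) %*% Z + lambda * Ainv))
  sol_direct <- solve(C, c(7, 7, 0, 0))
  expect_equal(unname(c(sol$b, sol$u)), unname(sol_direct), tolerance = 1e-10)
  # relatives receive half the parent deviation through the pedigree ties
  expect_equal(sol$u[["o1"]], sol$u[["o2"]])
})

test_that("genomic EBVs beat the estimated parent average on the simulated truth", {
  pop <- small_pop()
  ids <- pop$offspring_ids
  dat <- pop$phenotypes
  G <- condition_relmat(vanraden_grm(pop$genotypes[ids, ]), 0.01)
  fit <- animal_model(length_mm ~ cross, dat, G)
  u_true <- pop$true_bv[ids, 2]
  # comparator: parent average of pedigree-BLUP parental breeding values -
  # the between-family component only
  A <- pedigree_amat(pop$pedigree)
  fitA <- animal_model(length_mm ~ cross, dat, A)
  uA <- ebv(fitA)[, 1]
  ped <- pop$pedigree
  pa <- (uA[ped$sire[match(ids, ped$id)]] + uA[ped$dam[match(ids, ped$id)]]) / 2
  expect_gt(cor(ebv(fit)[ids, 1], u_true), cor(pa, u_true))
})

test_that("fold construction follows the training-remainder convention", {
  ids <- sprintf("x%04d", 1:1214)
  sch <- make_folds(ids, 5, 10, seed = 3)
  expect_equal(sch$n_validation, 242)
  expect_true(all(vapply(sch$folds, function(r)
    all(lengths(r) == 242), TRUE)))
  for (r in sch$folds) {
    expect_equal(anyDuplicated(unlist(r)), 0)
    # 972 training individuals complement each validation fold
    expect_true(all(vapply(r, function(v) length(setdiff(ids, v)), 0) == 972))
  }
  sch10 <- make_folds(letters[1:10], 5, 2, seed = 1)
  expect_true(all(lengths(sch10$folds[[1]]) == 2))
  expect_identical(make_folds(ids, 5, 3, seed = 9)$folds,
                   make_folds(ids, 5, 3, seed = 9)$folds)
  expect_error(make_folds(letters[1:3], 5), "fewer")
})

test_that("cross-validation accuracy behaves definitionally", {
  pop <- small_pop()
  ids <- pop$offspring_ids
  dat <- pop$phenotypes
  G <- condition_relmat(vanraden_grm(pop$genotypes[ids, ]), 0.01)
  sch <- make_folds(ids, 5, 2, seed = 5)
  cv <- cv_blup(length_mm ~ cross, dat, G, sch)
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(cv$folds$n_val == 50))
  expect_true(all(is.finite(cv$folds$accuracy)))
  # same scheme, same data: identical result
  cv2 <- cv_blup(length_mm ~ cross, dat, G, sch)
  expect_identical(cv$folds, cv2$folds)

  # location shift of the phenotype leaves accuracy and bias unchanged
  dat2 <- dat; dat2$length_mm <- dat$length_mm + 50
  cv3 <- cv_blup(length_mm ~ cross, dat2, G, sch)
  expect_equal(cv3$folds$accuracy, cv$folds$accuracy, tolerance = 1e-4)
  expect_equal(cv3$folds$bias, cv$folds$bias, tolerance = 1e-4)

  # unmasked information bound: EBV from an all-data fit predicts each
  # validation fold at least as well on average as the masked CV fit
  fit_all <- animal_model(length_mm ~ cross, dat, G)
  u_all <- ebv(fit_all)[, 1]
  h <- sqrt(fit_all$fit$h2)
  y <- setNames(dat$length_mm, dat$id)
  acc_unmasked <- mean(unlist(lapply(sch$folds, function(r)
    vapply(r, function(v) cor(u_all[v], y[v]) / h, 0))))
  expect_gt(acc_unmasked, cv$summary$mean_accuracy)
})

test_that("fixed components mode bypasses per-fold REML", {
  pop <- small_pop()
  ids <- pop$offspring_ids
  dat <- pop$phenotypes
  A <- pedigree_amat(pop$pedigree)
  sch <- make_folds(ids, 5, 1, seed = 6)
  cv <- cv_blup(length_mm ~ cross, dat, A, sch,
                components = list(sigma_g2 = 0.33 * 7.1^2,
                                  sigma_e2 = 0.67 * 7.1^2))
  expect_true(all(cv$folds$h2 == 0.33))
  expect_equal(cv$components, "fixed")
})

test_that("density scenarios share folds and keep panels nested", {
  pop <- small_pop()
  ids <- pop$offspring_ids
  dat <- pop$phenotypes
  g <- pop$genotypes[ids, ]
  sch <- make_folds(ids, 5, 2, seed = 7)
  cvt <- density_scenarios(length_mm ~ cross, dat, g,
                           pedigree = pop$pedigree,
                           thresholds = c(0.2, 0.4), scheme = sch)
  expect_setequal(names(cvt$results), c("FD", "maf0.2", "maf0.4", "PBLUP"))
  nm <- cvt$scenarios$n_markers
  expect_true(nm[1] >= nm[2] && nm[2] >= nm[3])
  expect_equal(dim(cvt$per_repeat), c(2, 4))
  # empty panel is skipped with a warning (restrict to low-MAF loci so the
  # 0.45 panel is empty by construction)
  low <- names(which(compute_maf(g) < 0.35))
  sch1 <- make_folds(ids, 5, 1, seed = 8)
  expect_warning(
    density_scenarios(length_mm ~ cross, dat, g[, low], pedigree = NULL,
                      thresholds = c(0.45), scheme = sch1),
    "skipped")
})
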