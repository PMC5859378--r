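# Trio Mendelian exclusion and parentage assignment.

test_that("trio incompatibility equals the gamete-enumeration oracle", {
  # oracle: offspring dosage possible iff it is a sum of one gamete from
  # each parent, with dosage 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  gametes <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  for (s in 0:2) for (d in 0:2) for (o in 0:2) {
    possible <- o %in% outer(gametes[[s + 1]], gametes[[d + 1]], "+")
    got <- trio_mismatch_rate(o, s, d)
    expect_equal(got$mismatches, as.integer(!possible),
                 info = sprintf("s=%d d=%d o=%d", s, d, o))
    expect_equal(got$compared, 1L)
  }
  # missing genotypes are skipped, never counted
  expect_equal(trio_mismatch_rate(c(2L, NA, 1L), c(0L, 0L, NA), c(0L, 0L, 1L)),
               list(rate = 1, mismatches = 1L, compared = 1L))
  expect_true(is.na(trio_mismatch_rate(NA_integer_, 0L, 0L)$rate))
})

test_that("constructed mismatch rates are counted exactly", {
  o <- rep(0L, 100); s <- rep(0L, 100); d <- rep(0L, 100)
  o[1:5] <- 2L
  expect_equal(trio_mismatch_rate(o, s, d)$rate, 0.05)
})

test_that("compiled all-pairs scan agrees with the single-trio path", {
  pop <- small_pop()
  g <- pop$genotypes_obs
  off <- g[pop$offspring_ids[1:12], ]
  si <- g[pop$sire_ids, ]
  da <- g[pop$dam_ids, ]
  res <- assign_parentage(off, si, da)
  a <- res$assignments
  for (i in c(1, 5, 12)) {
    tr <- trio_mismatch_rate(off[i, ], si[a$sire_id[i], ], da[a$dam_id[i], ])
    expect_equal(a$mismatch_rate[i], tr$rate)
    expect_equal(a$compared[i], tr$compared)
  }
})

test_that("error-free data give perfect unique assignment", {
  pop <- small_pop()
  g <- pop$genotypes
  res <- assign_parentage(g[pop$offspring_ids, ], g[pop$sire_ids, ],
                          g[pop$dam_ids, ], tolerance = 0)
  a <- res$assignments
  truth <- pop$pedigree[match(pop$offspring_ids, pop$pedigree$id), ]
  expect_true(all(a$status == "assigned"))
  expect_true(all(a$sire_id == truth$sire & a$dam_id == truth$dam))
  expect_true(all(a$mismatch_rate == 0))
})

test_that("a monozygotic duplicate sire forces ambiguity", {
  pop <- small_pop()
  g <- pop$genotypes
  si <- g[pop$sire_ids, ]
  dup <- si[rep(1, 2), ]
  rownames(dup) <- c(pop$sire_ids[1], "S_CLONE")
  si2 <- rbind(dup, si[-1, ])
  res <- assign_parentage(g[pop$offspring_ids, ], si2, g[pop$dam_ids, ])
  kids <- pop$pedigree$id[pop$pedigree$sire == pop$sire_ids[1]]
  st <- res$assignments$status[res$assignments$offspring_id %in% kids]
  expect_true(all(st == "ambiguous"))
  others <- res$assignments$status[!res$assignments$offspring_id %in% kids]
  expect_true(all(others == "assigned"))
})

test_that("raising the tolerance never loses assignments", {
  pop <- small_pop()
  obs <- apply_genotyping_noise(pop$genotypes, 0.03, 0.05, seed = 4)
  counts <- sapply(c(0.005, 0.02, 0.04, 0.1), function(tol) {
    r <- assign_parentage(obs[pop$offspring_ids, ], obs[pop$sire_ids, ],
                          obs[pop$dam_ids, ], tolerance = tol)
    r$summary$n_assigned
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("assignment is invariant to candidate order", {
  pop <- small_pop()
  g <- pop$genotypes_obs
  off <- g[pop$offspring_ids[1:25], ]
  r1 <- assign_parentage(off, g[pop$sire_ids, ], g[pop$dam_ids, ])
  perm_s <- sample(pop$sire_ids)
  perm_d <- rev(pop$dam_ids)
  r2 <- assign_parentage(off, g[perm_s, ], g[perm_d, ])
  expect_equal(r1$assignments[, c("sire_id", "dam_id", "status")],
               r2$assignments[, c("sire_id", "dam_id", "status")])
})

test_that("pedigree validation flags a swapped sire", {
  pop <- small_pop()
  g <- pop$genotypes
  ped <- pop$pedigree
  # swap one offspring's sire for a sire from another block
  off1 <- pop$offspring_ids[1]
  true_sire <- ped$sire[ped$id == off1]
  wrong <- setdiff(pop$sire_ids, ped$sire[ped$id == off1])
  wrong <- wrong[ped$block[match(wrong, ped$id)] != ped$block[ped$id == off1]][1]
  ped_bad <- ped
  ped_bad$sire[ped_bad$id == off1] <- wrong
  flags <- validate_pedigree(ped_bad, g, threshold = 0.02)
  bad_link <- flags[flags$offspring == off1 & flags$role == "sire", ]
  expect_true(bad_link$flagged)
  # expected opposing-homozygote rate vs an unrelated male: ~ mean(2 p^2 q^2)
  p <- colMeans(g[pop$founder_ids, ]) / 2
  expect_lt(abs(bad_link$rate - mean(2 * p^2 * (1 - p)^2)), 0.02)
  # everything else is clean, and a vacuous threshold flags nothing
  expect_equal(sum(flags$flagged), 1)
  expect_equal(sum(validate_pedigree(ped_bad, g, threshold = 1)$flagged), 0)
  expect_equal(sum(validate_pedigree(ped, g, threshold = 0.02)$flagged), 0)
})

test_that("trio mismatch under genotyping error matches the enumeration oracle", {
  # oracle: exact P(observed trio incompatible) for a true parent-offspring
  # trio at one locus with allele frequency p, each genotype independently
  # perturbed to a different dosage w.p. eps (uniform over the other two)
  eps <- 0.04
  err <- function(gt) {
    pr <- c(0, 0, 0); pr[gt + 1] <- 1 - eps
    pr[-(gt + 1)] <- pr[-(gt + 1)] + eps / 2
    pr
  }
  gametes <- list(`0` = c(1, 0), `1` = c(0.5, 0.5), `2` = c(0, 1))
  incompat <- function(s, d, o) {
    poss <- unique(as.vector(outer(which(gametes[[s + 1]] > 0) - 1,
                                   which(gametes[[d + 1]] > 0) - 1, "+")))
    !(o %in% poss)
  }
  oracle_rate <- function(p) {
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    tot <- 0
    for (s in 0:2) for (d in 0:2) {
      po <- gametes[[s + 1]] %o% gametes[[d + 1]]
      p_off <- c(po[1, 1], po[1, 2] + po[2, 1], po[2, 2])
      for (o in 0:2) {
        if (p_off[o + 1] == 0) next
        base <- hw[s + 1] * hw[d + 1] * p_off[o + 1]
        for (so in 0:2) for (do_ in 0:2) for (oo in 0:2) {
          pe <- err(s)[so + 1] * err(d)[do_ + 1] * err(o)[oo + 1]
          if (pe > 0 && incompat(so, do_, oo)) tot <- tot + base * pe
        }
      }
    }
    tot
  }
  pop <- small_pop()
  obs <- apply_genotyping_noise(pop$genotypes, error_rate = eps,
                                missing_rate = 0, seed = 11)
  ped <- pop$pedigree
  off <- pop$offspring_ids[1:150]
  rates <- vapply(off, function(o) {
    trio_mismatch_rate(obs[o, ], obs[ped$sire[ped$id == o], ],
                       obs[ped$dam[ped$id == o], ])$rate
  }, 0)
  p <- pop$marker_info$founder_freq
  expected <- mean(vapply(p, oracle_rate, 0))
  expect_lt(abs(mean(rates) - expected), 0.005)
})
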