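# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small population: 250 offspring, 600 markers, LE founders. Used by most
# module tests.
small_pop <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(n_offspring = 250, n_markers = 600, n_qtl = 120,
                      founder_generations = 0, seed = 42)
    .fixture_cache$small <- simulate_population(cfg)
  }
  .fixture_cache$small
}

# Study-scale population under the default (study) configuration. Heavy
# (~15 s); shared by the acceptance tests.
study_pop <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulate_population(sim_config(seed = 777000))
  }
  .fixture_cache$study
}

# Independent REML log-likelihood oracle: dense matrix algebra, no reuse of
# the package's rotated-space formulas.
reml_loglik_dense <- function(y, X, K, sg, se) {
  V <- sg * K + se * diag(length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y)))
}

# Independent recursive-kinship oracle (memoised); A = 2 * kinship.
kinship_oracle <- function(pedigree) {
  ids <- pedigree$id
  sire <- stats::setNames(pedigree$sire, ids)
  dam <- stats::setNames(pedigree$dam, ids)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (a == "0" || b == "0") return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ia <- match(a, ids); ib <- match(b, ids)
    val <- if (a == b) {
      0.5 * (1 + phi(sire[[a]], dam[[a]]))
    } else if (ia > ib) {
      0.5 * (phi(sire[[a]], b) + phi(dam[[a]], b))
    } else {
      0.5 * (phi(sire[[b]], a) + phi(dam[[b]], a))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i))
    K[i, j] <- K[j, i] <- phi(ids[i], ids[j])
  K
}

# Random multi-generation pedigree of n individuals (founders + offspring of
# already-created individuals), parents always precede offspring.
random_pedigree <- function(n, n_founders = 4, seed = 1) {
  set.seed(seed)
  id <- sprintf("I%02d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1):n) {
    pars <- sample(seq_len(i - 1), 2)
    sire[i] <- id[pars[1]]
    dam[i] <- id[pars[2]]
  }
  data.frame(id = id, sire = sire, dam = dam)
}
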