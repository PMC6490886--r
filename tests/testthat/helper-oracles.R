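# Independent brute-force oracles used to cross-check ordering, iteration
# and mass computation. Deliberately naive re-implementations: full
# permutation enumeration and direct step-map recursion over cycle-to-module
# assignments, with plain-vector scoring.

# all non-decreasing maps f: cycles -> modules with f(1)=1, f(n)=m and
# steps of 0 (stutter) or 1
oracle_maps <- function(n_modules, n_cycles) {
  res <- list()
  rec <- function(f) {
    i <- length(f)
    if (i == n_cycles) {
      if (f[i] == n_modules) res[[length(res) + 1L]] <<- f
      return(invisible())
    }
    for (step in 0:1) {
      nf <- f[i] + step
      if (nf <= n_modules && (n_modules - nf) <= (n_cycles - i - 1L))
        rec(c(f, nf))
    }
  }
  if (n_modules <= n_cycles) rec(1L)
  res
}

# plain-vector mismatch score; Inf when a stutter covers non-identical cycles
oracle_score <- function(mod, ext, f) {
  s <- 0
  for (i in seq_along(f)) {
    j <- f[i]
    if (i > 1L && f[i] == f[i - 1L]) {
      same <- identical(
        paste(ext$extender[i - 1L], ext$reduction[i - 1L],
              ext$alpha_stereo[i - 1L], ext$beta_stereo[i - 1L]),
        paste(ext$extender[i], ext$reduction[i],
              ext$alpha_stereo[i], ext$beta_stereo[i]))
      if (!same) return(Inf)
    }
    if (is.na(mod$at[j]) || mod$at[j] == "unknown") s <- s + 0.5
    else if (mod$at[j] != ext$extender[i]) s <- s + 1
    if (mod$red[j] != ext$reduction[i]) {
      s <- s + 1
    } else {
      pa <- if (mod$red[j] == "methylene") mod$er_alpha[j] else mod$kr_alpha[j]
      sd <- (!is.na(ext$alpha_stereo[i]) && !is.na(pa) &&
               pa != ext$alpha_stereo[i]) ||
        (!is.na(ext$beta_stereo[i]) && !is.na(mod$kr_beta[j]) &&
           mod$red[j] == "hydroxyl" && mod$kr_beta[j] != ext$beta_stereo[i])
      if (sd) s <- s + 0.5
    }
  }
  s
}

# exhaustive search over protein permutations x cycle maps.
# modules_df: the package module table; returns best score and the set of
# optimal (order, map) pairs.
oracle_best <- function(modules_df, target, loading_protein, te_protein) {
  proteins <- unique(modules_df$protein)
  perms <- list()
  permute <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (r in permute(x[-i])) out[[length(out) + 1L]] <- c(x[i], r)
    out
  }
  for (p in permute(proteins)) {
    if (!is.na(loading_protein) && p[1] != loading_protein) next
    if (!is.na(te_protein) && p[length(p)] != te_protein) next
    perms[[length(perms) + 1L]] <- p
  }
  ext <- target$extensions
  best <- Inf
  argmin <- list()
  for (p in perms) {
    md <- do.call(rbind, lapply(p, function(pr)
      modules_df[modules_df$protein == pr, , drop = FALSE]))
    mod <- list(at = md$at_substrate, red = md$reduction_level,
                er_alpha = md$er_alpha, kr_alpha = md$kr_alpha,
                kr_beta = md$kr_beta)
    for (f in oracle_maps(nrow(md), nrow(ext))) {
      s <- oracle_score(mod, ext, f)
      if (s < best) {
        best <- s
        argmin <- list(list(order = p, map = f, modules = md$module_id))
      } else if (is.finite(s) && s == best) {
        argmin[[length(argmin) + 1L]] <-
          list(order = p, map = f, modules = md$module_id)
      }
    }
  }
  list(score = best, optima = argmin)
}

# independent monoisotopic masses (IUPAC 2021 values, re-typed here)
oracle_mass <- function(formula) {
  m <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
         O = 15.9949146196, S = 31.97207100, P = 30.97376163)
  sum(as.numeric(formula[names(m)]) * m)
}

# build a pks_target directly from vectors
make_target <- function(extender, reduction, alpha = NA, beta = NA,
                        starter_carbons = 3L, starter_unit = "propionate",
                        site = NULL, name = "synthetic target") {
  n <- length(extender)
  ext <- data.frame(cycle = seq_len(n), extender = extender,
                    reduction = reduction,
                    alpha_stereo = rep_len(alpha, n),
                    beta_stereo = rep_len(beta, n),
                    confidence = "high", stringsAsFactors = FALSE)
  structure(list(name = name,
                 starter = list(unit = starter_unit,
                                carbons = starter_carbons),
                 cyclization_carbon = site, extensions = ext),
            class = "pks_target")
}

# target whose cycles are the planted module chemistry of a generated line,
# with one planted stutter (cycle duplicated)
target_from_truth <- function(line, stutter_at = NULL) {
  tm <- line$modules
  ext <- data.frame(extender = tm$at_substrate,
                    reduction = tm$reduction_level,
                    stringsAsFactors = FALSE)
  if (!is.null(stutter_at))
    ext <- ext[sort(c(seq_len(nrow(ext)), stutter_at)), , drop = FALSE]
  make_target(ext$extender, ext$reduction)
}
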