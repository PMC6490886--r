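#' Read a target-backbone description
#'
#' A target backbone lists the extension cycles (in synthesis order, cycle 1
#' first) a polyketide requires: extender unit, reduction state of the
#' beta-carbon processed in that cycle, and optional stereo labels; plus the
#' starter unit and the backbone carbon bearing the macrolactone hydroxyl.
#'
#' @param path YAML file.
#' @return A `pks_target`: list with `name`, `starter` (`unit`, `carbons`),
#'   `cyclization_carbon`, `extensions` (data.frame, one row per cycle).
#' @export
read_target <- function(path) {
  cfg <- yaml::read_yaml(path)
  ext <- do.call(rbind, lapply(cfg$extensions, function(e)
    data.frame(cycle = e$cycle,
               extender = e$extender,
               reduction = e$reduction,
               alpha_stereo = if (is.null(e$alpha_stereo)) NA_character_
                              else e$alpha_stereo,
               beta_stereo = if (is.null(e$beta_stereo)) NA_character_
                             else e$beta_stereo,
               confidence = if (is.null(e$confidence)) "high" else e$confidence,
               stringsAsFactors = FALSE)))
  ext <- ext[order(ext$cycle), , drop = FALSE]
  stopifnot(nrow(ext) >= 1L, identical(ext$cycle, seq_len(nrow(ext))))
  stopifnot(all(ext$extender %in%
                  c("malonyl", "methylmalonyl", "unusual-alkylmalonyl")))
  stopifnot(all(ext$reduction %in%
                  c("ketone", "hydroxyl", "enoyl", "methylene")))
  structure(list(name = cfg$name,
                 starter = cfg$starter,
                 cyclization_carbon = cfg$cyclization_carbon,
                 extensions = ext),
            class = "pks_target")
}

#' The packaged ossamycin target backbone
#'
#' Fifteen extension cycles on a propionate starter with macrolactonization
#' at C-23. Cells that are only figure-resident in the source (methyl
#' placement, some hydroxyl/stereo assignments) are marked
#' `confidence: low` in the fixture.
#'
#' @return A `pks_target`.
#' @export
ossamycin_target <- function() {
  read_target(system.file("extdata", "ossamycin_target.yaml",
                          package = "pksdecode", mustWork = TRUE))
}

#' The packaged ossamycin domain-call table
#'
#' Per-domain fingerprints for the eight PKS multienzymes OssA1-OssA8,
#' transcribed from the published active-site analysis: loading KSQ didomain
#' on OssA1, fourteen extension modules, thioesterase on OssA8, the
#' SPGH-variant AT of module 7, the His-to-Arg/His-to-Tyr substitutions that
#' inactivate DH1 and DH7, and the A1/A2/B1 ketoreductase complement.
#'
#' @return A `pks_calls` table (classified).
#' @export
ossamycin_domain_calls <- function() {
  df <- utils::read.delim(system.file("extdata", "ossamycin_domain_calls.tsv",
                                      package = "pksdecode", mustWork = TRUE),
                          stringsAsFactors = FALSE, comment.char = "#")
  df$partial <- FALSE
  classify_domains(df)
}

.reduction_level <- function(kr_present, kr_active, dh_present, dh_active,
                             er_present) {
  if (!kr_present || !isTRUE(kr_active)) return("ketone")
  if (!dh_present || !isTRUE(dh_active)) return("hydroxyl")
  if (!er_present) return("enoyl")
  "methylene"
}

#' Group domain calls into extension modules
#'
#' Applies the module grammar KS (AT) (DH) (ER) (KR) ACP along each protein,
#' recognizes an N-terminal KSQ-AT-ACP loading didomain and a chain-release
#' thioesterase, and derives each module's reduction level from its ACTIVE
#' domains (an inactive DH caps the module at hydroxyl, an inactive or
#' missing KR at ketone). Orphan domains make a module `malformed` (reported,
#' excluded from ordering).
#'
#' @param calls a `pks_calls` table (several proteins allowed); rows must be
#'   N-to-C ordered within each protein.
#' @return A `pks_line`: list with `loading` (NULL or list), `modules`
#'   (data.frame, one row per extension module, in protein order),
#'   `te_protein`, `per_protein` (module counts), `warnings`.
#' @export
build_modules <- function(calls) {
  if (is.null(calls$partial)) calls$partial <- FALSE
  calls <- calls[!(calls$partial %in% TRUE), , drop = FALSE]
  proteins <- unique(calls$protein)
  loading <- NULL
  te_protein <- NA_character_
  warnings <- character()
  mods <- list()

  for (prot in proteins) {
    rows <- calls[calls$protein == prot, , drop = FALSE]
    open <- NULL  # accumulating domain rows of the current module
    kind <- NULL  # "loading" or "extension"
    midx <- 0L
    close_module <- function(open, kind, complete) {
      types <- open$domain_type
      if (kind == "loading") {
        at <- open[types == "AT", , drop = FALSE]
        substrate <- if (nrow(at)) at$at_substrate[1] else NA_character_
        loading <<- list(protein = prot,
                         at_substrate = substrate,
                         starter_unit = switch(substrate,
                                               malonyl = "acetate",
                                               methylmalonyl = "propionate",
                                               "unknown"),
                         starter_carbons = switch(substrate,
                                                  malonyl = 2L,
                                                  methylmalonyl = 3L,
                                                  NA_integer_),
                         complete = complete)
        if (!complete)
          warnings <<- c(warnings, paste0("incomplete loading module on ", prot))
        return(invisible())
      }
      midx <<- midx + 1L
      at <- open[types == "AT", , drop = FALSE]
      kr <- open[types == "KR", , drop = FALSE]
      dh <- open[types == "DH", , drop = FALSE]
      er <- open[types == "ER", , drop = FALSE]
      malformed <- !complete || nrow(at) != 1L ||
        sum(types == "KS") != 1L || sum(types == "ACP") != 1L
      if (malformed)
        warnings <<- c(warnings, paste0("malformed module ", prot, "_m", midx,
                                        " (domains ",
                                        paste(types, collapse = "-"), ")"))
      kr_present <- nrow(kr) == 1L
      dh_present <- nrow(dh) == 1L
      er_present <- nrow(er) == 1L
      mods[[length(mods) + 1L]] <<- data.frame(
        module_id = paste0(prot, "_m", midx),
        protein = prot, index_in_protein = midx,
        domains = paste(types, collapse = "-"),
        at_substrate = if (nrow(at)) at$at_substrate[1] else NA_character_,
        at_rule = if (nrow(at)) at$at_rule[1] else NA_character_,
        at_discordant = if (nrow(at)) isTRUE(at$at_discordant[1]) else NA,
        kr_present = kr_present,
        kr_active = if (kr_present) isTRUE(kr$kr_active[1]) else FALSE,
        kr_type = if (kr_present) kr$kr_type[1] else NA_character_,
        kr_alpha = if (kr_present) kr$kr_alpha[1] else NA_character_,
        kr_beta = if (kr_present) kr$kr_beta[1] else NA_character_,
        kr_beta_dl = if (kr_present) kr$kr_beta_dl[1] else NA_character_,
        dh_present = dh_present,
        dh_active = if (dh_present) isTRUE(dh$dh_active[1]) else FALSE,
        dh_reason = if (dh_present) dh$dh_reason[1] else NA_character_,
        er_present = er_present,
        er_alpha = if (er_present) er$er_alpha[1] else NA_character_,
        reduction_level = .reduction_level(
          kr_present, if (kr_present) kr$kr_active[1] else FALSE,
          dh_present, if (dh_present) dh$dh_active[1] else FALSE,
          er_present),
        malformed = malformed,
        stringsAsFactors = FALSE)
      invisible()
    }

    for (i in seq_len(nrow(rows))) {
      type <- rows$domain_type[i]
      if (type %in% c("KS", "KSQ")) {
        if (!is.null(open)) close_module(open, kind, complete = FALSE)
        open <- rows[i, , drop = FALSE]
        kind <- if (type == "KSQ") "loading" else "extension"
      } else if (type == "ACP") {
        if (is.null(open)) {
          warnings <- c(warnings, paste0("orphan ACP on ", prot,
                                         " at position ", i))
          next
        }
        open <- rbind(open, rows[i, , drop = FALSE])
        close_module(open, kind, complete = TRUE)
        open <- NULL; kind <- NULL
      } else if (type == "TE") {
        te_protein <- prot
        if (!is.null(open)) {
          close_module(open, kind, complete = FALSE)
          open <- NULL
        }
      } else {
        if (is.null(open)) {
          warnings <- c(warnings, paste0("orphan ", type, " on ", prot,
                                         " at position ", i))
          next
        }
        open <- rbind(open, rows[i, , drop = FALSE])
      }
    }
    if (!is.null(open)) close_module(open, kind, complete = FALSE)
  }

  modules <- if (length(mods)) do.call(rbind, mods) else NULL
  per_protein <- if (!is.null(modules))
    table(factor(modules$protein, levels = proteins)) else table(character())
  for (w in warnings) warning(w, call. = FALSE)
  structure(list(loading = loading, modules = modules,
                 te_protein = te_protein,
                 per_protein = stats::setNames(as.integer(per_protein),
                                               names(per_protein)),
                 warnings = warnings),
            class = "pks_line")
}

#' @export
print.pks_line <- function(x, ...) {
  n <- if (is.null(x$modules)) 0L else sum(!x$modules$malformed)
  cat("PKS assembly line:", n, "extension module(s)",
      if (!is.null(x$loading)) paste0("+ loading (", x$loading$starter_unit,
                                      " starter)") else "(no loading module)",
      if (!is.na(x$te_protein)) paste0("+ TE on ", x$te_protein) else "", "\n")
  if (!is.null(x$modules))
    print.data.frame(x$modules[, c("module_id", "domains", "at_substrate",
                                   "kr_type", "reduction_level", "malformed")])
  invisible(x)
}

# per-cycle mismatch between a module's predicted chemistry and a target cycle
.cycle_mismatches <- function(module, cycle_row, weights) {
  out <- list()
  mext <- module$at_substrate
  if (is.na(mext) || mext == "unknown") {
    out[[length(out) + 1L]] <- list(field = "extender", module_value = mext,
                                    target_value = cycle_row$extender,
                                    weight = weights["unknown"])
  } else if (mext != cycle_row$extender) {
    out[[length(out) + 1L]] <- list(field = "extender", module_value = mext,
                                    target_value = cycle_row$extender,
                                    weight = weights["extender"])
  }
  if (module$reduction_level != cycle_row$reduction) {
    out[[length(out) + 1L]] <- list(field = "reduction",
                                    module_value = module$reduction_level,
                                    target_value = cycle_row$reduction,
                                    weight = weights["reduction"])
  } else {
    # stereo compared only when chemistry otherwise agrees and labels defined
    pred_alpha <- if (module$reduction_level == "methylene") module$er_alpha
      else module$kr_alpha
    stereo_diff <-
      (!is.na(cycle_row$alpha_stereo) && !is.na(pred_alpha) &&
         pred_alpha != cycle_row$alpha_stereo) ||
      (!is.na(cycle_row$beta_stereo) && !is.na(module$kr_beta) &&
         module$reduction_level == "hydroxyl" &&
         module$kr_beta != cycle_row$beta_stereo)
    if (stereo_diff)
      out[[length(out) + 1L]] <- list(field = "stereo",
                                      module_value = paste(pred_alpha,
                                                           module$kr_beta),
                                      target_value = paste(cycle_row$alpha_stereo,
                                                           cycle_row$beta_stereo),
                                      weight = weights["stereo"])
  }
  out
}

.default_weights <- c(extender = 1, reduction = 1, stereo = 0.5, unknown = 0.5)

# all ways to distribute k extra (stutter) cycles over m modules
.compositions <- function(m, k) {
  if (choose(m + k - 1, k) > 1e5)
    stop("too many stutter placements to enumerate (", m, " modules, ",
         k, " extra cycles)")
  if (k == 0L) return(list(integer(m)))
  out <- list()
  rec <- function(prefix, left, pos) {
    if (pos == m) {
      out[[length(out) + 1L]] <<- c(prefix, left)
      return(invisible())
    }
    for (e in 0:left) rec(c(prefix, e), left - e, pos + 1L)
  }
  rec(integer(0), k, 1L)
  out
}

.target_cycles_identical <- function(ext, idx) {
  cols <- c("extender", "reduction", "alpha_stereo", "beta_stereo")
  sub <- ext[idx, cols, drop = FALSE]
  all(vapply(sub, function(v) length(unique(ifelse(is.na(v), "<na>", v))) == 1L,
             TRUE))
}

# score one stutter composition; returns NULL if inadmissible
.score_assignment <- function(modules, target, extra, weights) {
  ext <- target$extensions
  reps <- 1L + extra
  cycle_module <- rep(seq_len(nrow(modules)), times = reps)
  # stutters must cover chemically identical consecutive target cycles
  for (j in which(extra > 0L)) {
    covered <- which(cycle_module == j)
    if (!.target_cycles_identical(ext, covered)) return(NULL)
  }
  score <- 0
  mismatches <- list()
  for (cyc in seq_len(nrow(ext))) {
    mm <- .cycle_mismatches(modules[cycle_module[cyc], , drop = FALSE],
                            ext[cyc, , drop = FALSE], weights)
    for (m in mm) {
      score <- score + m$weight
      mismatches[[length(mismatches) + 1L]] <-
        data.frame(cycle = cyc, module_id = modules$module_id[cycle_module[cyc]],
                   field = m$field, module_value = m$module_value,
                   target_value = m$target_value, weight = m$weight,
                   stringsAsFactors = FALSE)
    }
  }
  list(extra = extra, cycle_to_module = modules$module_id[cycle_module],
       score = score,
       mismatches = if (length(mismatches)) do.call(rbind, mismatches)
                    else NULL)
}

#' Detect programmed iteration (module stuttering)
#'
#' Maps target extension cycles onto physical modules. With as many cycles as
#' modules the mapping is the identity; with `k` more cycles than modules, all
#' assignments in which some module(s) perform consecutive, chemically
#' identical cycles are enumerated, scored by total chemistry mismatch
#' (extender 1, reduction 1, stereo-only 0.5), and the best is returned with
#' any ties reported (tie-break: earliest stuttered cycle).
#'
#' @param modules module data.frame (rows in assembly-line order; malformed
#'   modules excluded by the caller) — e.g. `line$modules` after ordering.
#' @param target a `pks_target`.
#' @param weights mismatch weights.
#' @return A `pks_iteration`: list with `cycle_to_module`, `iterated_modules`,
#'   `stutters` (data.frame module/cycles), `score`, `ties` (count of equally
#'   scored placements), `discrepancies` (per-cycle mismatch table).
#' @export
detect_iteration <- function(modules, target, weights = .default_weights) {
  m <- nrow(modules)
  n <- nrow(target$extensions)
  if (n < m)
    stop("surplus modules: ", m, " physical modules for ", n,
         " target cycles")
  k <- n - m
  cands <- list()
  for (extra in .compositions(m, k)) {
    sc <- .score_assignment(modules, target, extra, weights)
    if (!is.null(sc)) cands[[length(cands) + 1L]] <- sc
  }
  if (length(cands) == 0L)
    stop("no consistent stutter assignment: no run of ", k + 1L,
         " consecutive target cycles is chemically identical where required")
  scores <- vapply(cands, `[[`, 0, "score")
  best_score <- min(scores)
  ties <- cands[scores == best_score]
  # earliest stuttered cycle wins
  first_stutter <- vapply(ties, function(a) {
    w <- which(a$extra > 0L)
    if (length(w) == 0L) 0L else min(which(duplicated(a$cycle_to_module))) - 1L
  }, 0L)
  best <- ties[[order(first_stutter)[1]]]
  stut_modules <- modules$module_id[best$extra > 0L]
  stutters <- if (length(stut_modules))
    data.frame(module_id = stut_modules,
               cycles = vapply(stut_modules, function(id)
                 paste(which(best$cycle_to_module == id), collapse = ","), ""),
               stringsAsFactors = FALSE)
  else NULL
  structure(list(cycle_to_module = best$cycle_to_module,
                 iterated_modules = stut_modules,
                 stutters = stutters,
                 score = best_score,
                 ties = length(ties),
                 tied_assignments = lapply(ties, `[[`, "cycle_to_module"),
                 discrepancies = best$mismatches),
            class = "pks_iteration")
}

#' @export
print.pks_iteration <- function(x, ...) {
  cat("Cycle-to-module assignment (", length(x$cycle_to_module), " cycles, ",
      length(unique(x$cycle_to_module)), " modules, score ", x$score, ")\n",
      sep = "")
  if (length(x$iterated_modules))
    cat("Iterated module(s):",
        paste0(x$stutters$module_id, " -> cycles ", x$stutters$cycles,
               collapse = "; "), "\n")
  else cat("No iteration (identity mapping)\n")
  if (!is.null(x$discrepancies)) {
    cat("Discrepancies:\n")
    print.data.frame(x$discrepancies)
  }
  if (x$ties > 1L) cat("Note:", x$ties, "equally scored assignments (ties reported)\n")
  invisible(x)
}

#' Infer the assembly-line order of multienzymes
#'
#' The loading-module protein is pinned first and the thioesterase protein
#' last; the remaining proteins are permuted exhaustively and each candidate
#' order is scored by its best iteration assignment against the target
#' backbone ([detect_iteration()]). The minimal-score order is returned.
#'
#' @param line a `pks_line` from [build_modules()].
#' @param target a `pks_target`.
#' @param weights mismatch weights.
#' @return Character vector of protein ids in assembly-line order, with
#'   attributes `score`, `ties` (equally scored orders) and `iteration` (the
#'   `pks_iteration` for the best order).
#' @export
order_multienzymes <- function(line, target, weights = .default_weights) {
  modules <- line$modules[!line$modules$malformed, , drop = FALSE]
  proteins <- unique(modules$protein)
  first <- if (!is.null(line$loading)) line$loading$protein else NA_character_
  last <- line$te_protein
  if (is.na(first) && is.na(last))
    stop("ordering ambiguous: no loading module and no thioesterase found; ",
         "candidates: ", paste(proteins, collapse = ", "))
  middle <- setdiff(proteins, c(first, last))
  if (length(middle) > 8L)
    stop("exhaustive ordering supports at most 8 unpinned proteins")
  perms <- .permutations(middle)
  best <- NULL
  best_orders <- list()
  for (p in perms) {
    ord <- c(if (!is.na(first)) first, p, if (!is.na(last) && !identical(last, first)) last)
    mods <- do.call(rbind, lapply(ord, function(pr)
      modules[modules$protein == pr, , drop = FALSE]))
    it <- tryCatch(detect_iteration(mods, target, weights),
                   error = function(e) NULL)
    if (is.null(it)) next
    first_stutter <- if (length(it$iterated_modules) == 0L) Inf
      else min(which(duplicated(it$cycle_to_module)))
    if (is.null(best) || it$score < best$score ||
        (it$score == best$score && first_stutter < best$first_stutter)) {
      newly_best <- is.null(best) || it$score < best$score
      prev_orders <- if (newly_best) list() else best_orders
      best <- it; best$order <- ord; best$first_stutter <- first_stutter
      best_orders <- c(prev_orders, list(ord))
    } else if (it$score == best$score) {
      best_orders[[length(best_orders) + 1L]] <- ord
    }
  }
  if (is.null(best))
    stop("no protein order admits a consistent cycle assignment")
  structure(best$order, score = best$score, ties = best_orders,
            iteration = best[setdiff(names(best), "order")])
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 0L) return(list(character(0)))
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
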