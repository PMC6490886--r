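# Line-notation (SMILES) export of the macrolactone model, plus a small
# formula-from-SMILES counter used to round-trip the emitted notation against
# the internal elemental bookkeeping.
#
# Stereocentre marks are annotations mapping the model's configuration labels
# onto @/@@ by a fixed convention (beta 3R -> @@, 3S -> @; alpha 2S -> @,
# 2R -> @@); they flag where a configuration is assigned, and are not a CIP
# perception.

.sugar_smiles_branch <- function(digit) {
  # 2,3,4,6-tetradeoxy-4-(N,N-dimethylamino)hexopyranosyl, O-linked
  sprintf("(OC%dCCC(N(C)C)C(C)O%d)", digit, digit)
}

#' Export a macrolactone as a SMILES-style line notation
#'
#' Emits the macrocycle C-1..C-ring-site with the ester closure, all chain
#' substituents and oxidation states, tailoring hydroxyls, the spiroacetal
#' and side-chain hemiacetal rings where the corresponding events were
#' applied, and the O-linked deoxyaminosugar where a glycosylation event was
#' applied. The emitted string round-trips: [formula_from_smiles()] on the
#' output equals the model's formula.
#'
#' @param mac a `pks_macrolactone`.
#' @param stereo include stereo annotations where configurations are
#'   assigned.
#' @return Character scalar.
#' @export
export_structure <- function(mac, stereo = TRUE) {
  chain <- mac$chain
  n_bb <- chain$backbone_carbon_count
  units <- chain$units
  site <- mac$lactone_oxygen_carbon

  oh_extra <- integer(n_bb)        # tailoring hydroxyls on backbone carbons
  glyco_at <- integer(0)
  spiro <- NULL
  hemi <- FALSE
  side_oh <- FALSE
  for (ev in mac$tailoring) {
    carbon <- .site_carbon(ev$site)
    if (ev$kind == "hydroxylation") {
      if (!is.na(carbon) && carbon <= n_bb) oh_extra[carbon] <- oh_extra[carbon] + 1L
      else side_oh <- TRUE         # side-chain hydroxylation (label beyond backbone)
    } else if (ev$kind == "glycosylation") {
      if (!is.na(carbon) && carbon <= n_bb) glyco_at <- c(glyco_at, carbon)
    } else if (ev$kind == "spiroacetal" &&
               identical(ev$convention, "ketal") && !is.null(ev$partners)) {
      partners <- vapply(ev$partners, .site_carbon, 0L)
      if (!is.na(carbon) && all(!is.na(partners)))
        spiro <- list(center = carbon, p = sort(partners))
    } else if (ev$kind == "hemiacetal") {
      hemi <- TRUE
    }
  }
  hemi_center <- if (hemi && side_oh) {
    uu <- units[units$alpha_substituent == "isobutyl", , drop = FALSE]
    if (nrow(uu)) uu$beta_carbon[1] else NA_integer_
  } else NA_integer_

  bond_before <- rep("", n_bb)
  for (c in seq_len(chain$n_cycles))
    if (units$beta_state[c] == "enoyl")
      bond_before[units$beta_carbon[c]] <- "="

  token <- character(n_bb)
  for (i in seq_len(n_bb)) {
    state <- chain$carbon_states[paste0("C", i)]
    u_alpha <- units[units$alpha_carbon == i, , drop = FALSE]
    atom <- "C"
    branches <- character(0)
    # a tailoring hydroxyl or the sugar removes the H a stereo bracket
    # would pin, so stereo marks are only emitted on undecorated carbons
    decorated <- oh_extra[i] > 0L || i %in% glyco_at

    if (i == 1L) {
      token[i] <- "O=C1"
      next
    }
    if (!is.na(state)) {                       # carbonyl-position carbon
      if (identical(unname(state), "ketone")) {
        if (!is.null(spiro) && spiro$center == i) {
          branches <- c(branches, "3", "4")    # ring closures to the two acetal O
        } else if (!is.na(hemi_center) && hemi_center == i) {
          branches <- c(branches, "6", "(O)")
        } else branches <- c(branches, "(=O)")
      } else if (identical(unname(state), "hydroxyl")) {
        if (i == site) {
          branches <- c(branches, "(O1)")
        } else if (!is.null(spiro) && i %in% spiro$p) {
          branches <- c(branches,
                        sprintf("(O%d)", if (i == spiro$p[1]) 3L else 4L))
        } else {
          branches <- c(branches, "(O)")
          if (stereo && !decorated) {
            ub <- units[units$beta_carbon == i, , drop = FALSE]
            if (nrow(ub) && !is.na(ub$beta_stereo[1]))
              atom <- if (ub$beta_stereo[1] == "3R") "[C@@H]" else "[C@H]"
          }
        }
      }
    }
    if (nrow(u_alpha)) {
      subst <- u_alpha$alpha_substituent[1]
      if (subst == "methyl") {
        branches <- c(branches, "(C)")
        if (stereo && !decorated && !is.na(u_alpha$alpha_stereo[1]))
          atom <- if (u_alpha$alpha_stereo[1] == "2S") "[C@H]" else "[C@@H]"
      } else if (subst == "isobutyl") {
        side <- if (!is.na(hemi_center)) "(CC(C)CO6)"
          else if (side_oh) "(CC(C)CO)" else "(CC(C)C)"
        branches <- c(branches, side)
      }
    }
    n_oh <- oh_extra[i]
    if (i %in% glyco_at) {
      branches <- c(branches, .sugar_smiles_branch(7L))
      n_oh <- n_oh - 1L                        # the sugar replaces one hydroxyl
      if (n_oh < 0L) {
        # glycosylation consumed the chain hydroxyl instead
        branches <- setdiff(branches, "(O)")
        n_oh <- 0L
      }
    }
    if (n_oh > 0L) branches <- c(branches, rep("(O)", n_oh))
    # ring-closure digits must precede parenthesised branches
    digits <- branches[!grepl("^\\(", branches)]
    parens <- branches[grepl("^\\(", branches)]
    token[i] <- paste0(atom, paste(digits, collapse = ""),
                       paste(parens, collapse = ""))
  }
  paste0(paste0(bond_before, token, collapse = ""), "")
}

#' Elemental formula from a SMILES string
#'
#' A minimal SMILES reader sufficient for the notations this package emits
#' (and for simple organic SMILES generally): element atoms C/N/O/S/P,
#' bracket atoms with explicit hydrogens and @/@@ marks, branches,
#' single-digit ring closures, and =/# bonds. Implicit hydrogens are filled
#' to standard valences (C 4, N 3, O 2, S 2, P 3).
#'
#' @param s SMILES string.
#' @return A `pks_formula`.
#' @export
formula_from_smiles <- function(s) {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3)
  chars <- strsplit(s, "")[[1]]
  elements <- character(0)
  expl_h <- integer(0)
  bond_sum <- numeric(0)
  prev <- NA_integer_
  pending <- 1
  stack <- integer(0)
  ring <- list()
  i <- 1L
  new_atom <- function(el, h) {
    elements[length(elements) + 1L] <<- el
    expl_h[length(expl_h) + 1L] <<- h
    bond_sum[length(bond_sum) + 1L] <<- 0
    idx <- length(elements)
    if (!is.na(prev)) {
      bond_sum[prev] <<- bond_sum[prev] + pending
      bond_sum[idx] <<- bond_sum[idx] + pending
    }
    pending <<- 1
    prev <<- idx
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      el <- regmatches(inner, regexpr("^[A-Z][a-z]?", inner))
      hmatch <- regmatches(inner, regexpr("H[0-9]*", inner))
      h <- if (length(hmatch) == 0L) 0L
        else if (hmatch == "H") 1L
        else as.integer(sub("H", "", hmatch))
      new_atom(el, h)
      i <- j + 1L
    } else if (ch %in% names(valence)) {
      new_atom(ch, NA_integer_)
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(ring[[key]])) {
        other <- ring[[key]]
        bond_sum[prev] <- bond_sum[prev] + other$order
        bond_sum[other$atom] <- bond_sum[other$atom] + other$order
        ring[[key]] <- NULL
      } else {
        ring[[key]] <- list(atom = prev, order = pending)
      }
      pending <- 1
      i <- i + 1L
    } else stop("unsupported SMILES character: ", ch)
  }
  if (length(ring)) stop("unclosed ring bond(s) in SMILES")
  implicit <- ifelse(is.na(expl_h),
                     pmax(0, valence[elements] - bond_sum),
                     expl_h)
  counts <- tapply(rep(1L, length(elements)), elements, sum)
  args <- as.list(counts)
  args$H <- (if (is.null(args$H)) 0L else args$H) + sum(implicit)
  do.call(chem_formula, args)
}
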