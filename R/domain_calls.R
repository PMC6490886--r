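# Fingerprint-to-call rules for AT, KR, DH and ER domains.
#
# The rules are deliberately literal transcriptions of the published motif
# grammar: AT extender choice from the active-site serine motif (GHSQ vs
# GHS[ILV]) together with the second-histidine motif (HAFH vs YASH, or a
# small-residue variant such as SPGH/VASH for exotic alkylmalonyl units); KR
# activity from the catalytic Tyr with the Lys/Ser pair as supporting
# evidence, stereotype from the LDD Asp (B-type) or Trp (A-type) and the
# His-for-Gln substitution (A2); DH activity from the His of Hxxx(G/D)xxxxPG
# plus the Asp of Dxxx(Q/H); ER alpha-carbon outcome from the Tyr motif.

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", X = "Xaa")

.small_residues <- c("G", "A", "S", "P", "V", "C", "T")

.check_hit <- function(hit, type) {
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1L)
      stop("expected a single domain hit, got ", nrow(hit))
    if (!hit$domain_type %in% type)
      stop("contract violation: classify_", tolower(type[1]),
           "() called on a ", hit$domain_type, " hit")
  }
  invisible(TRUE)
}

#' Call AT extender-unit specificity from fingerprint motifs
#'
#' @param hit a one-row AT hit from [scan_domains()], or the 4-residue
#'   active-site serine motif (e.g. `"GHSQ"`).
#' @param second_motif the 4-residue second-histidine motif (e.g. `"HAFH"`);
#'   ignored when `hit` is a data.frame.
#' @return A list: `substrate` (one of malonyl, methylmalonyl,
#'   unusual-alkylmalonyl, unknown), `rule` (rule id that fired),
#'   `discordant` (TRUE when the two motifs each match but disagree),
#'   and the two observed motifs.
#' @export
#' @examples
#' classify_at("GHSQ", "HAFH")$substrate   # malonyl
#' classify_at("GHSI", "YASH")$substrate   # methylmalonyl
#' classify_at("GHSV", "SPGH")$substrate   # unusual-alkylmalonyl
classify_at <- function(hit, second_motif = NULL) {
  if (is.data.frame(hit)) {
    .check_hit(hit, "AT")
    ser <- hit$at_ser4
    sec <- hit$at_sec
  } else {
    ser <- hit
    sec <- second_motif
  }
  stopifnot(is.character(ser), is.character(sec))
  ser_class <- if (!grepl("^GHS", ser)) "unknown"
    else switch(substr(ser, 4, 4),
                Q = "malonyl", I = , L = , V = "methylmalonyl", "unknown")
  sec_class <-
    if (identical(sec, "HAFH")) "malonyl"
    else if (identical(sec, "YASH")) "methylmalonyl"
    else if (nchar(sec) == 4L && substr(sec, 4, 4) == "H" &&
             all(strsplit(substr(sec, 1, 3), "")[[1]] %in% .small_residues))
      "unusual-alkylmalonyl"
    else "unknown"

  if (sec_class == "unusual-alkylmalonyl" && grepl("^GHS", ser)) {
    out <- list(substrate = "unusual-alkylmalonyl",
                rule = paste0("at_unusual_variant_", sec), discordant = FALSE)
  } else if (ser_class == "malonyl" && sec_class == "malonyl") {
    out <- list(substrate = "malonyl", rule = "at_malonyl_GHSQ_HAFH",
                discordant = FALSE)
  } else if (ser_class == "methylmalonyl" && sec_class == "methylmalonyl") {
    out <- list(substrate = "methylmalonyl", rule = "at_methylmalonyl_GHSx_YASH",
                discordant = FALSE)
  } else {
    disc <- ser_class != "unknown" && sec_class != "unknown" &&
      ser_class != sec_class
    out <- list(substrate = "unknown",
                rule = if (disc) "at_discordant_motifs" else "at_no_rule",
                discordant = disc)
  }
  c(out, list(serine_motif = ser, second_motif = sec))
}

#' Call KR activity, stereotype and product configuration
#'
#' Activity requires the catalytic Tyr; a missing Lys or Ser downgrades
#' confidence but not the call. Stereotype: Asp as third residue of an
#' LDD-like motif gives B1; a Trp gives A-type, subdivided into A2 when the
#' His-for-Gln substitution is present, otherwise A1. Product configuration
#' labels follow the published A1/A2/B1 mapping; the A2 alpha label is
#' configurable because the published A2 and B1 labels coincide, which is
#' flagged in the call.
#'
#' @param hit one-row KR hit from [scan_domains()], or a named list/vector
#'   with elements `kr_tyr`, `kr_lys`, `kr_ser`, `kr_ldd`, `kr_trp`, `kr_qh`.
#' @param a2_alpha alpha-carbon label for A2-type KRs (default as published).
#' @return A list: `active`, `kr_type` (A1/A2/B1/unknown), `alpha_config`,
#'   `beta_config`, `beta_dl` (d/l hydroxyacyl label), `confidence`, `note`.
#' @export
classify_kr <- function(hit, a2_alpha = "2R") {
  if (is.data.frame(hit)) .check_hit(hit, "KR")
  g <- function(nm) as.character(hit[[nm]])
  tyr <- g("kr_tyr"); lys <- g("kr_lys"); ser <- g("kr_ser")
  ldd <- g("kr_ldd"); trp <- g("kr_trp"); qh <- g("kr_qh")
  active <- identical(tyr, "Y")
  confidence <- if (active && identical(lys, "K") && identical(ser, "S"))
    "high" else if (active) "reduced" else "none"
  if (!active) {
    return(list(active = FALSE, kr_type = "unknown", alpha_config = NA_character_,
                beta_config = NA_character_, beta_dl = NA_character_,
                confidence = confidence,
                note = paste0("catalytic Tyr absent (Tyr→",
                              .aa3[[substr(tyr, 1, 1)]], ")")))
  }
  kr_type <- if (nchar(ldd) == 3L && substr(ldd, 3, 3) == "D") "B1"
    else if (identical(trp, "W")) { if (identical(qh, "H")) "A2" else "A1" }
    else "unknown"
  alpha <- switch(kr_type, A1 = "2S", A2 = a2_alpha, B1 = "2R", NA_character_)
  beta <- switch(kr_type, A1 = "3R", A2 = "3R", B1 = "3R", NA_character_)
  dl <- switch(kr_type, A1 = , A2 = "l", B1 = "d", NA_character_)
  note <- if (kr_type == "A2")
    "A2 stereo label kept as published; published A2 and B1 labels coincide"
  else NA_character_
  list(active = TRUE, kr_type = kr_type, alpha_config = alpha,
       beta_config = beta, beta_dl = dl, confidence = confidence, note = note)
}

#' Call DH activity from the His and Asp motifs
#'
#' @param hit one-row DH hit from [scan_domains()], or the His-motif residue;
#'   in the latter case supply `asp`.
#' @param asp the Asp-motif residue (single character).
#' @return A list: `active`, `reason` (names the substitution when inactive).
#' @export
#' @examples
#' classify_dh("R", "D")$reason  # "His->Arg"
classify_dh <- function(hit, asp = NULL) {
  if (is.data.frame(hit)) {
    .check_hit(hit, "DH")
    his <- hit$dh_his; asp <- hit$dh_asp
  } else his <- hit
  stopifnot(is.character(his), is.character(asp))
  if (his == "H" && asp == "D")
    return(list(active = TRUE, reason = "His and Asp motifs intact"))
  reason <- c(
    if (his != "H") paste0("His→", .aa3[[his]]),
    if (asp != "D") paste0("Asp→", .aa3[[asp]]))
  list(active = FALSE, reason = paste(reason, collapse = "; "))
}

#' Call ER alpha-carbon stereochemical outcome
#'
#' @param hit one-row ER hit from [scan_domains()], or the Tyr-motif residue.
#' @return A list: `present`, `alpha_outcome` ("2S" with the Tyr motif, "2R"
#'   without; "n/a" when no ER hit is supplied).
#' @export
classify_er <- function(hit) {
  if (is.null(hit) || (is.data.frame(hit) && nrow(hit) == 0L))
    return(list(present = FALSE, alpha_outcome = "n/a"))
  if (is.data.frame(hit)) {
    .check_hit(hit, "ER")
    tyr <- hit$er_tyr
  } else tyr <- hit
  list(present = TRUE, alpha_outcome = if (identical(tyr, "Y")) "2S" else "2R")
}

#' Classify every domain hit in a scan table
#'
#' Applies the AT/KR/DH/ER rules to each non-partial hit and returns the
#' table augmented with call columns. Partial hits keep NA calls.
#'
#' @param hits data.frame from [scan_domains()] (or a call-table fixture with
#'   the same fingerprint columns).
#' @param a2_alpha passed to [classify_kr()].
#' @return The input with added columns `at_substrate`, `at_rule`,
#'   `at_discordant`, `kr_active`, `kr_type`, `kr_alpha`, `kr_beta`,
#'   `kr_beta_dl`, `kr_confidence`, `dh_active`, `dh_reason`, `er_alpha`.
#'   Class `pks_calls`.
#' @export
classify_domains <- function(hits, a2_alpha = "2R") {
  n <- nrow(hits)
  hits$at_substrate <- NA_character_
  hits$at_rule <- NA_character_
  hits$at_discordant <- NA
  hits$kr_active <- NA
  hits$kr_type <- NA_character_
  hits$kr_alpha <- NA_character_
  hits$kr_beta <- NA_character_
  hits$kr_beta_dl <- NA_character_
  hits$kr_confidence <- NA_character_
  hits$dh_active <- NA
  hits$dh_reason <- NA_character_
  hits$er_alpha <- NA_character_
  if (is.null(hits$partial)) hits$partial <- FALSE
  for (i in seq_len(n)) {
    if (isTRUE(hits$partial[i])) next
    type <- hits$domain_type[i]
    if (type == "AT") {
      call <- classify_at(hits$at_ser4[i], hits$at_sec[i])
      hits$at_substrate[i] <- call$substrate
      hits$at_rule[i] <- call$rule
      hits$at_discordant[i] <- call$discordant
    } else if (type == "KR") {
      call <- classify_kr(hits[i, , drop = FALSE], a2_alpha = a2_alpha)
      hits$kr_active[i] <- call$active
      hits$kr_type[i] <- call$kr_type
      hits$kr_alpha[i] <- call$alpha_config
      hits$kr_beta[i] <- call$beta_config
      hits$kr_beta_dl[i] <- call$beta_dl
      hits$kr_confidence[i] <- call$confidence
    } else if (type == "DH") {
      call <- classify_dh(hits[i, , drop = FALSE])
      hits$dh_active[i] <- call$active
      hits$dh_reason[i] <- call$reason
    } else if (type == "ER") {
      call <- classify_er(hits[i, , drop = FALSE])
      hits$er_alpha[i] <- call$alpha_outcome
    }
  }
  class(hits) <- c("pks_calls", "data.frame")
  hits
}

#' @export
print.pks_calls <- function(x, ...) {
  cat("PKS domain call table:", nrow(x), "domains on",
      length(unique(x$protein)), "protein(s)\n")
  shown <- c("protein", "domain_type", "at_substrate", "kr_type",
             "dh_active", "er_alpha")
  print.data.frame(x[, intersect(shown, names(x))], ...)
  invisible(x)
}
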