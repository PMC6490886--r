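#' Locate PKS catalytic domains in a multienzyme sequence
#'
#' Scans a protein sequence against the packaged anchor profiles
#' ([pks_profiles()]) and reports located domains N-terminus to C-terminus,
#' with active-site fingerprint residues extracted at fixed offsets from each
#' anchor. Domains whose template span is truncated by a protein end are
#' flagged `partial` and are excluded from downstream classification.
#'
#' @param protein character scalar, amino-acid sequence (20-letter alphabet,
#'   `X` tolerated), or a named character vector of several proteins.
#' @param profiles profile set from [pks_profiles()].
#' @param protein_id identifier used in the output when `protein` is a scalar.
#' @return A data.frame of domain hits: `protein`, `domain_type`, `start`,
#'   `end` (1-based inclusive), `anchor_pos`, `partial`, plus one column per
#'   fingerprint slot (NA where not applicable).
#' @export
scan_domains <- function(protein, profiles = pks_profiles(),
                         protein_id = "protein1") {
  if (length(protein) > 1L) {
    ids <- names(protein)
    if (is.null(ids)) ids <- paste0("protein", seq_along(protein))
    out <- mapply(function(s, id) scan_domains(s, profiles, id),
                  protein, ids, SIMPLIFY = FALSE)
    return(do.call(rbind, c(out, list(make.row.names = FALSE))))
  }
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", protein))
    stop("illegal character(s) in protein sequence ", protein_id)
  n <- nchar(protein)

  rows <- list()
  for (pf in profiles) {
    m <- gregexpr(pf$anchor_regex, protein)[[1]]
    if (m[1] == -1L) next
    for (p in as.integer(m)) {
      origin <- p - (pf$anchor_start - 1L)
      start <- origin
      end <- origin + pf$length - 1L
      partial <- start < 1L || end > n
      row <- data.frame(protein = protein_id, domain_type = pf$type,
                        start = max(1L, start), end = min(n, end),
                        anchor_pos = p, partial = partial,
                        stringsAsFactors = FALSE)
      for (col in .slot_columns) row[[col]] <- NA_character_
      if (!partial) {
        for (nm in names(pf$slots)) {
          sl <- pf$slots[[nm]]
          pos <- origin + sl$offset - 1L
          row[[nm]] <- substr(protein, pos, pos + sl$length - 1L)
        }
        # the AT serine fingerprint is reported as the 4-residue GHS+x motif
        if (pf$type == "AT")
          row$at_ser4 <- substr(protein, origin + pf$slots$at_ser4$offset - 4L,
                                origin + pf$slots$at_ser4$offset - 1L)
        if (pf$type == "KS" && !is.na(row$ksq) && row$ksq == "Q")
          row$domain_type <- "KSQ"
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(protein = character(), domain_type = character(),
                      start = integer(), end = integer(),
                      anchor_pos = integer(), partial = logical(),
                      stringsAsFactors = FALSE)
    for (col in .slot_columns) out[[col]] <- character()
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  # enforce non-overlap: keep the earlier hit on conflict
  keep <- rep(TRUE, nrow(out))
  last_end <- -1L
  for (i in seq_len(nrow(out))) {
    if (out$start[i] <= last_end) keep[i] <- FALSE
    else last_end <- out$end[i]
  }
  if (any(!keep))
    warning("dropped ", sum(!keep), " overlapping domain hit(s) in ", protein_id)
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}
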