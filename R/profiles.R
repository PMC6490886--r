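# Anchored active-site profiles for PKS catalytic domains.
#
# Each profile is a compact reference block for one domain type: a template
# string, an anchor (a conserved literal run with classification slots shown as
# wildcards) used to locate the domain, and named slots at fixed offsets from
# the template origin holding the active-site fingerprint residues.  Real PKS
# domains run to several hundred residues; these blocks are desk-scale proxies
# that carry the same diagnostic residues in conserved context, and the slot
# offsets are configuration, not hard-coded biology.

.lit <- function(s) list(kind = "lit", s = s)
.slot <- function(name, default) list(kind = "slot", name = name, default = default)

# assemble a profile from pieces; anchor_pieces indexes the contiguous run of
# pieces whose span is used for scanning (slots inside become "." wildcards)
.mk_profile <- function(type, pieces, anchor_pieces, fingerprints) {
  template <- ""
  slots <- list()
  starts <- integer(length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    starts[i] <- nchar(template) + 1L
    s <- if (p$kind == "lit") p$s else p$default
    if (p$kind == "slot")
      slots[[p$name]] <- list(offset = starts[i], length = nchar(p$default))
    template <- paste0(template, s)
  }
  a0 <- starts[min(anchor_pieces)]
  last <- max(anchor_pieces)
  a1 <- starts[last] + nchar(if (pieces[[last]]$kind == "lit") pieces[[last]]$s
                             else pieces[[last]]$default) - 1L
  anchor <- substr(template, a0, a1)
  # wildcard the slot positions that fall inside the anchor
  regex_chars <- strsplit(anchor, "")[[1]]
  for (sl in slots) {
    idx <- seq(sl$offset, sl$offset + sl$length - 1L) - a0 + 1L
    idx <- idx[idx >= 1 & idx <= length(regex_chars)]
    regex_chars[idx] <- "."
  }
  list(type = type,
       template = template,
       length = nchar(template),
       anchor_start = a0,
       anchor_regex = paste(regex_chars, collapse = ""),
       slots = slots,
       fingerprints = fingerprints)
}

#' Reference anchor profiles for PKS domain scanning
#'
#' Returns the packaged set of per-domain anchor profiles used by
#' [scan_domains()] and by the synthetic-sequence generator. Each profile
#' carries a template block, an anchor regular expression, and fixed-offset
#' fingerprint slots (e.g. the AT active-site serine motif, the KR catalytic
#' triad and LDD/Trp stereotype residues). The KS profile doubles as the KSQ
#' detector: a glutamine in the catalytic-cysteine slot types the domain as a
#' decarboxylating loading-module KSQ.
#'
#' @param file optional YAML file overriding slot offsets/templates; the file
#'   must have the same structure as the packaged default.
#' @return Named list of profiles (KS, AT, DH, ER, KR, ACP, TE).
#' @export
pks_profiles <- function(file = NULL) {
  if (!is.null(file)) {
    cfg <- yaml::read_yaml(file)
    return(cfg)
  }
  list(
    KS = .mk_profile("KS",
      list(.lit("EPVAIVGIGCRFPGGV"),
           .lit("GVDTA"), .slot("ksq", "C"), .lit("SSSLVAVHLA"),
           .lit("CQSLRSGESDLALAGGVTVMSSPGAF")),
      anchor_pieces = 2:4,
      fingerprints = list(KS_Q_substitution = "ksq")),
    AT = .mk_profile("AT",
      list(.lit("VFVFPGQGSQWAGMGAELL"),
           .lit("ESLMGHS"), .slot("at_ser4", "Q"), .lit("GEYAAHVA"),
           .lit("GVLSLEDAARLVALRGRLMQ"),
           .lit("RVD"), .slot("at_sec", "HAFH"), .lit("SPLMEP"),
           .lit("VLSGQP")),
      anchor_pieces = 2:4,
      fingerprints = list(AT_serine_motif = "at_ser4",
                          AT_second_his_motif = "at_sec")),
    DH = .mk_profile("DH",
      list(.lit("PGVLSGTVELP"),
           .lit("GRFLA"), .slot("dh_his", "H"), .lit("ALLGDAVLPG"),
           .lit("VETELNLRA"),
           .lit("GQP"), .slot("dh_asp", "D"), .lit("LVMQ"),
           .lit("AVALLPRAA")),
      anchor_pieces = 2:4,
      fingerprints = list(DH_his_motif = "dh_his", DH_asp_motif = "dh_asp")),
    ER = .mk_profile("ER",
      list(.lit("TLRPDGQAVLT"),
           .lit("GAAGGVGS"), .slot("er_tyr", "Y"), .lit("AVQLAKRA"),
           .lit("GDRVFLASA")),
      anchor_pieces = 2:4,
      fingerprints = list(ER_tyr_motif = "er_tyr")),
    KR = .mk_profile("KR",
      list(.lit("GTYLITGGTGGLGLQVA"),
           .lit("RWLVEQGA"),
           .slot("kr_ldd", "LDD"), .lit("GQTVL"),
           .slot("kr_trp", "W"), .lit("SRSGA"),
           .slot("kr_qh", "Q"), .lit("EPVA"),
           .slot("kr_lys", "K"), .lit("GLA"),
           .slot("kr_ser", "S"), .lit("TVA"),
           .slot("kr_tyr", "Y"), .lit("AANAFLDALA")),
      anchor_pieces = 1,
      fingerprints = list(KR_LDD_motif = "kr_ldd", KR_A_trp = "kr_trp",
                          KR_A2_his_for_gln = "kr_qh", KR_lys = "kr_lys",
                          KR_ser = "kr_ser", KR_catalytic_tyr = "kr_tyr")),
    ACP = .mk_profile("ACP",
      list(.lit("IEERLA"),
           .lit("GLLGFDSLTAVELRNRLA"),
           .lit("ATSLA")),
      anchor_pieces = 2,
      fingerprints = list()),
    TE = .mk_profile("TE",
      list(.lit("QPLA"),
           .lit("RLFCFPHAGGSASAFRA"),
           .lit("WSELA")),
      anchor_pieces = 2,
      fingerprints = list())
  )
}

# slot columns reported by scan_domains / expected in call-table fixtures
.slot_columns <- c("ksq", "at_ser4", "at_sec", "dh_his", "dh_asp",
                   "kr_ldd", "kr_trp", "kr_qh", "kr_lys", "kr_ser", "kr_tyr",
                   "er_tyr")
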