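# Small in-code fixtures for unit tests.

# build a call table row-by-row: domain type plus any fingerprint slots
make_calls <- function(protein, domains) {
  slot_cols <- c("ksq", "at_ser4", "at_sec", "dh_his", "dh_asp", "kr_ldd",
                 "kr_trp", "kr_qh", "kr_lys", "kr_ser", "kr_tyr", "er_tyr")
  rows <- lapply(domains, function(d) {
    row <- data.frame(protein = protein, domain_type = d$type,
                      partial = FALSE, stringsAsFactors = FALSE)
    for (col in slot_cols) row[[col]] <- NA_character_
    for (nm in setdiff(names(d), "type")) row[[nm]] <- d[[nm]]
    row
  })
  classify_domains(do.call(rbind, rows))
}

d_ks  <- function() list(type = "KS", ksq = "C")
d_ksq <- function() list(type = "KSQ", ksq = "Q")
d_acp <- function() list(type = "ACP")
d_te  <- function() list(type = "TE")
d_at  <- function(ser = "GHSQ", sec = "HAFH")
  list(type = "AT", at_ser4 = ser, at_sec = sec)
d_dh  <- function(his = "H", asp = "D")
  list(type = "DH", dh_his = his, dh_asp = asp)
d_er  <- function(tyr = "Y") list(type = "ER", er_tyr = tyr)
d_kr  <- function(ldd = "LDD", trp = "L", qh = "Q", tyr = "Y",
                  lys = "K", ser = "S")
  list(type = "KR", kr_ldd = ldd, kr_trp = trp, kr_qh = qh,
       kr_lys = lys, kr_ser = ser, kr_tyr = tyr)

# a tiny synthetic GenBank flat file (two CDS features)
write_mini_genbank <- function(path) {
  writeLines(c(
    "LOCUS       SYNCLUSTER              3000 bp    DNA     linear   BCT",
    "DEFINITION  synthetic mini cluster.",
    "FEATURES             Location/Qualifiers",
    "     source          1..3000",
    "     CDS             1..903",
    "                     /gene=\"mgA\"",
    "                     /product=\"Polyketide synthase\"",
    "                     /protein_id=\"SYN00001.1\"",
    "     CDS             1001..2203",
    "                     /gene=\"mgB\"",
    "                     /product=\"Cytochrome P450\"",
    "                     /protein_id=\"SYN00002.1\"",
    "ORIGIN",
    "//"), path)
  path
}
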