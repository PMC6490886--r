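# Synthetic PKS multienzyme generator with planted ground truth.
#
# Domain blocks are emitted from the same packaged anchor profiles the
# scanner uses, with the classification slots set to the planted call and
# everything outside anchors/slots free to vary: flanking linkers are drawn
# from a fixed amino-acid background frequency (not uniform, to keep
# composition realistic), and block positions outside the anchor and slots
# are mutated at a configurable rate. A collision check re-draws any protein
# in which a spurious anchor match appears.

# Robinson-Robinson-style background amino-acid frequencies
.aa_background <- c(A = .078, R = .051, N = .045, D = .054, C = .019,
                    Q = .043, E = .063, G = .074, H = .022, I = .051,
                    L = .091, K = .057, M = .022, F = .039, P = .052,
                    S = .071, T = .058, W = .013, Y = .032, V = .065)

.mix_seed <- function(seed, i) {
  ((as.numeric(seed) %% 2^31) * 48271 + i * 7919) %% 2147483647
}

#' Specify one planted extension module
#'
#' @param at planted AT specificity: `"malonyl"`, `"methylmalonyl"`,
#'   `"unusual"`.
#' @param kr NULL (no KR domain) or one of `"A1"`, `"A2"`, `"B1"`,
#'   `"inactive"`.
#' @param dh NULL (no DH) or `"active"`, `"his_arg"`, `"his_tyr"`.
#' @param er NULL (no ER) or `"tyr"`, `"no_tyr"`.
#' @return A module spec (list), validated.
#' @export
module_spec <- function(at = "malonyl", kr = NULL, dh = NULL, er = NULL) {
  if (!at %in% c("malonyl", "methylmalonyl", "unusual"))
    stop("unrealizable module spec: unknown AT substrate ", at)
  if (!is.null(kr) && !kr %in% c("A1", "A2", "B1", "inactive"))
    stop("unrealizable module spec: unknown KR state ", kr)
  if (!is.null(dh) && !dh %in% c("active", "his_arg", "his_tyr"))
    stop("unrealizable module spec: unknown DH state ", dh)
  if (!is.null(er) && !er %in% c("tyr", "no_tyr"))
    stop("unrealizable module spec: unknown ER state ", er)
  list(at = at, kr = kr, dh = dh, er = er)
}

#' Generator configuration
#'
#' @param seed integer seed; the same seed and configuration give
#'   byte-identical output.
#' @param proteins list (one element per protein) of lists of
#'   [module_spec()]s (module-to-protein packing).
#' @param loading NULL or the AT substrate of a KSQ loading didomain placed
#'   at the N-terminus of the first protein (`"methylmalonyl"` gives a
#'   propionate starter).
#' @param te place a thioesterase at the C-terminus of the last protein.
#' @param linker_range inter-domain linker length range (residues).
#' @param decoy_count number of additional domain-free decoy proteins.
#' @param mutation_rate per-residue substitution rate applied outside
#'   anchors and fingerprint slots.
#' @return A generator config (list).
#' @export
generator_config <- function(seed, proteins, loading = "methylmalonyl",
                             te = TRUE, linker_range = c(15L, 40L),
                             decoy_count = 0L, mutation_rate = 0.05) {
  stopifnot(length(proteins) >= 1L, all(lengths(proteins) >= 0L))
  lapply(proteins, function(mods) lapply(mods, function(m)
    do.call(module_spec, m)))  # validate
  if (!is.null(loading) && !loading %in% c("malonyl", "methylmalonyl"))
    stop("loading AT must be malonyl or methylmalonyl")
  list(seed = as.integer(seed), proteins = proteins, loading = loading,
       te = te, linker_range = as.integer(linker_range),
       decoy_count = as.integer(decoy_count), mutation_rate = mutation_rate)
}

.sample_linker <- function(range) {
  len <- sample(seq(range[1], range[2]), 1L)
  paste(sample(names(.aa_background), len, replace = TRUE,
               prob = .aa_background), collapse = "")
}

# emit one domain block: template with slot values planted, mutations outside
# anchor/slots
.emit_block <- function(profile, slot_values, mutation_rate) {
  chars <- strsplit(profile$template, "")[[1]]
  protected <- rep(FALSE, length(chars))
  a0 <- profile$anchor_start
  protected[seq(a0, a0 + nchar(profile$anchor_regex) - 1L)] <- TRUE
  for (nm in names(profile$slots)) {
    sl <- profile$slots[[nm]]
    idx <- seq(sl$offset, sl$offset + sl$length - 1L)
    protected[idx] <- TRUE
    if (!is.null(slot_values[[nm]])) {
      val <- strsplit(slot_values[[nm]], "")[[1]]
      stopifnot(length(val) == sl$length)
      chars[idx] <- val
    }
  }
  if (mutation_rate > 0) {
    mut <- which(!protected & stats::runif(length(chars)) < mutation_rate)
    if (length(mut))
      chars[mut] <- sample(names(.aa_background), length(mut),
                           replace = TRUE, prob = .aa_background)
  }
  paste(chars, collapse = "")
}

.at_slots <- function(at) {
  switch(at,
         malonyl = list(at_ser4 = "Q", at_sec = "HAFH"),
         methylmalonyl = list(at_ser4 = sample(c("I", "L", "V"), 1L),
                              at_sec = "YASH"),
         unusual = list(at_ser4 = "V", at_sec = sample(c("SPGH", "VASH"), 1L)))
}

.kr_slots <- function(kr) {
  switch(kr,
         A1 = list(kr_ldd = "AGA", kr_trp = "W", kr_qh = "Q",
                   kr_lys = "K", kr_ser = "S", kr_tyr = "Y"),
         A2 = list(kr_ldd = "AGA", kr_trp = "W", kr_qh = "H",
                   kr_lys = "K", kr_ser = "S", kr_tyr = "Y"),
         B1 = list(kr_ldd = "LDD", kr_trp = "L", kr_qh = "Q",
                   kr_lys = "K", kr_ser = "S", kr_tyr = "Y"),
         inactive = list(kr_ldd = "LDD", kr_trp = "L", kr_qh = "Q",
                         kr_lys = "K", kr_ser = "S", kr_tyr = "F"))
}

.dh_slots <- function(dh) {
  switch(dh,
         active = list(dh_his = "H", dh_asp = "D"),
         his_arg = list(dh_his = "R", dh_asp = "D"),
         his_tyr = list(dh_his = "Y", dh_asp = "D"))
}

#' Emit a synthetic assembly line with planted ground truth
#'
#' @param config from [generator_config()].
#' @return List with `proteins` (named character vector of sequences),
#'   `truth` (data.frame: one row per planted domain with its interval and
#'   planted fingerprints), `modules` (data.frame: one row per planted
#'   module with its expected calls and reduction level), `config`.
#' @export
emit_line <- function(config) {
  profiles <- pks_profiles()
  all_seqs <- character(0)
  truth_rows <- list()
  module_rows <- list()

  n_prot <- length(config$proteins)
  for (pi in seq_len(n_prot)) {
    set.seed(.mix_seed(config$seed, pi))
    pname <- sprintf("synpks%02d", pi)
    for (attempt in 1:25) {
      blocks <- list()   # list of (type, seq, slots)
      add_block <- function(type, slots = list()) {
        profile <- profiles[[if (type == "KSQ") "KS" else type]]
        if (type == "KSQ") slots$ksq <- "Q"
        if (type == "KS") slots$ksq <- "C"
        blocks[[length(blocks) + 1L]] <<-
          list(type = type,
               seq = .emit_block(profile, slots, config$mutation_rate),
               slots = slots)
      }
      if (pi == 1L && !is.null(config$loading)) {
        add_block("KSQ")
        add_block("AT", .at_slots(config$loading))
        add_block("ACP")
      }
      for (m in config$proteins[[pi]]) {
        m <- do.call(module_spec, m)
        add_block("KS")
        add_block("AT", .at_slots(m$at))
        if (!is.null(m$dh)) add_block("DH", .dh_slots(m$dh))
        if (!is.null(m$er)) add_block("ER",
          list(er_tyr = if (m$er == "tyr") "Y" else "V"))
        if (!is.null(m$kr)) add_block("KR", .kr_slots(m$kr))
        add_block("ACP")
      }
      if (pi == n_prot && isTRUE(config$te)) add_block("TE")

      seq <- .sample_linker(config$linker_range)
      intervals <- list()
      for (b in blocks) {
        start <- nchar(seq) + 1L
        seq <- paste0(seq, b$seq)
        intervals[[length(intervals) + 1L]] <-
          c(start = start, end = nchar(seq))
        seq <- paste0(seq, .sample_linker(config$linker_range))
      }
      # collision check: every profile must match exactly its planted count
      expected <- table(vapply(blocks, function(b)
        if (b$type == "KSQ") "KS" else b$type, ""))
      clean <- TRUE
      for (pf_name in names(profiles)) {
        m <- gregexpr(profiles[[pf_name]]$anchor_regex, seq)[[1]]
        found <- if (m[1] == -1L) 0L else length(m)
        want <- if (pf_name %in% names(expected)) expected[[pf_name]] else 0L
        if (found != want) { clean <- FALSE; break }
      }
      if (clean) break
      if (attempt == 25L)
        stop("could not emit a collision-free sequence for ", pname)
    }
    all_seqs[pname] <- seq

    # ground truth rows
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      row <- data.frame(protein = pname, block = k, domain_type = b$type,
                        start = unname(intervals[[k]]["start"]),
                        end = unname(intervals[[k]]["end"]),
                        stringsAsFactors = FALSE)
      for (col in .slot_columns) row[[col]] <- NA_character_
      for (nm in names(b$slots)) row[[nm]] <- b$slots[[nm]]
      if (b$type == "AT")
        row$at_ser4 <- paste0("GHS", b$slots$at_ser4)
      truth_rows[[length(truth_rows) + 1L]] <- row
    }
    midx <- 0L
    for (m in config$proteins[[pi]]) {
      m <- do.call(module_spec, m)
      midx <- midx + 1L
      kr_active <- !is.null(m$kr) && m$kr != "inactive"
      dh_active <- !is.null(m$dh) && m$dh == "active"
      module_rows[[length(module_rows) + 1L]] <- data.frame(
        protein = pname, index_in_protein = midx,
        at_substrate = switch(m$at, malonyl = "malonyl",
                              methylmalonyl = "methylmalonyl",
                              unusual = "unusual-alkylmalonyl"),
        kr_type = if (kr_active) m$kr else
          if (!is.null(m$kr)) "unknown" else NA_character_,
        kr_active = if (is.null(m$kr)) NA else kr_active,
        dh_active = if (is.null(m$dh)) NA else dh_active,
        er_present = !is.null(m$er),
        er_alpha = if (!is.null(m$er)) {
          if (m$er == "tyr") "2S" else "2R"
        } else NA_character_,
        reduction_level = .reduction_level(!is.null(m$kr), kr_active,
                                           !is.null(m$dh), dh_active,
                                           !is.null(m$er)),
        stringsAsFactors = FALSE)
    }
  }

  # decoys: shuffled background sequence, guaranteed anchor-free
  if (config$decoy_count > 0L) {
    profiles_rx <- vapply(profiles, `[[`, "", "anchor_regex")
    for (d in seq_len(config$decoy_count)) {
      set.seed(.mix_seed(config$seed, 1000L + d))
      repeat {
        seq <- paste(sample(names(.aa_background), 400L, replace = TRUE,
                            prob = .aa_background), collapse = "")
        if (!any(vapply(profiles_rx, function(rx) grepl(rx, seq), TRUE)))
          break
      }
      all_seqs[sprintf("decoy%02d", d)] <- seq
    }
  }

  list(proteins = all_seqs,
       truth = do.call(rbind, truth_rows),
       modules = do.call(rbind, module_rows),
       config = config)
}

#' Write generator output as FASTA
#'
#' @param line output of [emit_line()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_line_fasta <- function(line, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(line$proteins), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(line$proteins))
      writeLines(c(paste0(">", nm), line$proteins[[nm]]), con)
  }
  invisible(path)
}

#' Read protein FASTA as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  stopifnot(length(idx) > 0L)
  ends <- c(idx[-1] - 1L, length(lines))
  stats::setNames(
    vapply(seq_along(idx), function(i)
      paste(lines[(idx[i] + 1L):ends[i]], collapse = ""), ""),
    sub("^>\\s*(\\S+).*$", "\\1", lines[idx]))
}

#' Emit a synthetic cluster annotation table consistent with a line
#'
#' One row per emitted PKS multienzyme (true emitted lengths), plus
#' configurable accessory genes.
#'
#' @param config generator config.
#' @param line optional pre-computed [emit_line()] output (re-emitted when
#'   NULL).
#' @param accessory data.frame with columns `name`, `proposed_function`
#'   (e.g. P450s, sugar genes, regulator, transporter); NULL for a PKS-only
#'   table.
#' @return A `pks_cluster`.
#' @export
emit_cluster_table <- function(config, line = NULL, accessory = NULL) {
  if (is.null(line)) line <- emit_line(config)
  pks <- data.frame(name = names(line$proteins),
                    length_aa = nchar(line$proteins),
                    proposed_function = "Polyketide synthase",
                    ncbi_hit = NA_character_, accession = NA_character_,
                    stringsAsFactors = FALSE)
  pks$proposed_function[grepl("^decoy", pks$name)] <- "Hypothetical protein"
  df <- pks
  if (!is.null(accessory)) {
    acc <- data.frame(name = accessory$name,
                      length_aa = if (is.null(accessory$length_aa))
                        rep(300L, nrow(accessory)) else accessory$length_aa,
                      proposed_function = accessory$proposed_function,
                      ncbi_hit = NA_character_, accession = NA_character_,
                      stringsAsFactors = FALSE)
    df <- rbind(df, acc)
  }
  set.seed(.mix_seed(config$seed, 99L))
  df$gene_id <- .assign_gene_ids(df$name, df$proposed_function)
  df <- df[, c("gene_id", "name", "length_aa", "proposed_function",
               "ncbi_hit", "accession")]
  structure(df, source = "fixture", class = c("pks_cluster", "data.frame"))
}

#' Generator configuration mimicking the ossamycin assembly line
#'
#' Fourteen extension modules over eight multienzymes with the published
#' complement: KSQ loading didomain (methylmalonyl AT, propionate starter),
#' inactive DH in modules 1 (His-to-Arg) and 7 (His-to-Tyr), KR-less
#' modules 4 and 7, the unusual-alkylmalonyl AT in module 7, the A2-type KR
#' in module 6, enoylreductases in modules 3, 9, 10, 11, 12, and a
#' chain-release thioesterase.
#'
#' @param seed integer seed.
#' @param mutation_rate per-residue substitution rate outside anchors.
#' @return A generator config.
#' @export
ossamycin_mimic_config <- function(seed = 1L, mutation_rate = 0.05) {
  m <- function(...) list(...)
  generator_config(
    seed = seed,
    proteins = list(
      list(m(at = "methylmalonyl", kr = "B1", dh = "his_arg"),          # m1
           m(at = "methylmalonyl", kr = "A1")),                         # m2
      list(m(at = "malonyl", kr = "B1", dh = "active", er = "tyr"),     # m3
           m(at = "methylmalonyl")),                                    # m4
      list(m(at = "malonyl", kr = "B1"),                                # m5
           m(at = "methylmalonyl", kr = "A2"),                          # m6
           m(at = "unusual", dh = "his_tyr")),                          # m7
      list(m(at = "malonyl", kr = "B1", dh = "active")),                # m8
      list(m(at = "malonyl", kr = "B1", dh = "active", er = "tyr")),    # m9 (9/10)
      list(m(at = "methylmalonyl", kr = "B1", dh = "active", er = "tyr")), # m10 (11)
      list(m(at = "malonyl", kr = "B1", dh = "active", er = "tyr"),     # m11
           m(at = "malonyl", kr = "B1", dh = "active", er = "tyr")),    # m12
      list(m(at = "malonyl", kr = "A1"),                                # m13
           m(at = "methylmalonyl", kr = "B1"))),                        # m14
    loading = "methylmalonyl", te = TRUE,
    mutation_rate = mutation_rate)
}

#' Accessory-gene set mimicking the ossamycin cluster census
#'
#' @return data.frame usable as `accessory` in [emit_cluster_table()]:
#'   19 genes (thioesterase, regulator, CCR, FabH-like, four P450s,
#'   spirocyclase, six sugar genes, glycosyltransferase, transporter, two
#'   others) that with 8 PKS genes give a 27-gene cluster.
#' @export
mimic_accessory_genes <- function() {
  data.frame(
    name = c("synTE2", "synREG", "synCCR", "synFABH",
             "synP450a", "synP450b", "synP450c", "synP450d",
             "synSPIRO", "synS", "synT", "synQ", "synZ", "synJ", "synI",
             "synGT", "synTRANS", "synX1", "synX2"),
    proposed_function = c(
      "Thioesterase", "LuxR family transcriptional regulator",
      "Crotonyl-CoA reductase", "Ketoacyl-ACP synthase III",
      "Cytochrome P450", "Cytochrome P450", "Cytochrome P450",
      "Cytochrome P450", "Spirocyclase",
      "NDP-hexose-2,3-dehydratase", "NDP-hexose-3-ketoreductase",
      "NDP-hexose 3,4-dehydratase",
      "dTDP-4-keto-6-deoxyhexose 3,5-epimerase",
      "dTDP-4-amino-4,6-dideoxygalactose transaminase",
      "SAM-dependent methyltransferase", "Glycosyltransferase",
      "ABC transporter", "Hypothetical protein",
      "serine hydroxymethyltransferase"),
    stringsAsFactors = FALSE)
}
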