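#' Read a gene-cluster annotation table
#'
#' Reads a cluster annotation into a `pks_cluster` object: one record per
#' annotated CDS/row, input order preserved. Three dialects are supported:
#' a TSV with columns `name`, `length_aa`, `proposed_function` and optional
#' `ncbi_hit`, `accession`; a GenBank flat file (CDS features; 1-based
#' inclusive coordinates per GenBank convention); and GFF3 (CDS/gene
#' features, read through rtracklayer).
#'
#' Duplicated display names (annotation tables sometimes reuse a label for
#' two unrelated genes) are kept verbatim but receive stable internal ids:
#' a duplicate whose function matches a sugar-pathway keyword gets the
#' suffix `_sugar`, a transporter `_transport`, and anything else `_2`,
#' `_3`, ...
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"genbank"`, `"gff"`.
#' @return A `pks_cluster`: data.frame with columns `gene_id`, `name`,
#'   `length_aa`, `proposed_function`, `ncbi_hit`, `accession`, and
#'   attribute `source`.
#' @export
read_cluster_table <- function(path, format = c("tsv", "genbank", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- switch(format,
                  tsv = .read_cluster_tsv(path),
                  genbank = .read_cluster_genbank(path),
                  gff = .read_cluster_gff(path))
  if (nrow(genes) == 0L) stop("no gene records in ", path)
  if (any(!is.finite(genes$length_aa)) || any(genes$length_aa <= 0))
    stop("length_aa must be a positive integer for every gene")
  genes$gene_id <- .assign_gene_ids(genes$name, genes$proposed_function)
  genes <- genes[, c("gene_id", "name", "length_aa", "proposed_function",
                     "ncbi_hit", "accession")]
  structure(genes, source = format, class = c("pks_cluster", "data.frame"))
}

.read_cluster_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", quote = "")
  need <- c("name", "length_aa", "proposed_function")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("malformed cluster TSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(is.na(df$name) | df$name == "" |
                 is.na(suppressWarnings(as.numeric(df$length_aa))))
  if (length(bad))
    stop("malformed row(s) in ", path, " at data line(s) ",
         paste(bad, collapse = ", "))
  df$length_aa <- as.integer(df$length_aa)
  if (is.null(df$ncbi_hit)) df$ncbi_hit <- rep(NA_character_, nrow(df))
  if (is.null(df$accession)) df$accession <- rep(NA_character_, nrow(df))
  df[, c("name", "length_aa", "proposed_function", "ncbi_hit", "accession")]
}

# minimal GenBank flat-file CDS reader (offline; feature table only)
.read_cluster_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0L) stop("not a GenBank flat file: ", path)
  end <- grep("^(ORIGIN|//)", lines)
  end <- if (length(end)) min(end[end > feat_start[1]]) - 1L else length(lines)
  feats <- lines[(feat_start[1] + 1L):end]
  cds_idx <- grep("^\\s{5}CDS\\s", feats)
  if (length(cds_idx) == 0L) stop("no CDS features in ", path)
  recs <- vector("list", length(cds_idx))
  bounds <- c(cds_idx, length(feats) + 1L)
  for (k in seq_along(cds_idx)) {
    block <- feats[cds_idx[k]:(bounds[k + 1L] - 1L)]
    # stop at the next feature key within the block
    keys <- grep("^\\s{5}\\S", block)
    if (length(keys) > 1L) block <- block[1:(keys[2] - 1L)]
    loc <- sub("^\\s{5}CDS\\s+", "", block[1])
    span <- regmatches(loc, regexpr("[0-9]+\\.\\.[0-9]+", loc))[1]
    if (is.na(span)) stop("malformed CDS location in ", path, ": ", loc)
    coords <- as.integer(strsplit(span, "\\.\\.")[[1]])
    qual <- function(name) {
      i <- grep(paste0('^\\s+/', name, '='), block)
      if (length(i) == 0L) return(NA_character_)
      gsub('^[^=]*="?|"$', "", block[i[1]])
    }
    name <- qual("gene")
    if (is.na(name)) name <- qual("locus_tag")
    if (is.na(name)) name <- paste0("cds_", k)
    translation <- qual("translation")
    len <- if (!is.na(translation)) nchar(gsub("[^A-Za-z]", "", translation))
      else (diff(coords) + 1L) %/% 3L - 1L  # 1-based inclusive, minus stop
    recs[[k]] <- data.frame(name = name, length_aa = as.integer(len),
                            proposed_function = ifelse(is.na(qual("product")),
                                                       "", qual("product")),
                            ncbi_hit = NA_character_,
                            accession = qual("protein_id"),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

.read_cluster_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("CDS", "gene")]
  if (length(gr) == 0L) stop("no CDS/gene features in ", path)
  meta <- as.data.frame(gr)
  getcol <- function(nm) if (nm %in% names(meta)) as.character(meta[[nm]])
    else rep(NA_character_, nrow(meta))
  name <- getcol("Name")
  name[is.na(name)] <- getcol("ID")[is.na(name)]
  data.frame(name = name,
             length_aa = as.integer(meta$width %/% 3L - 1L),
             proposed_function = ifelse(is.na(getcol("product")), "",
                                        getcol("product")),
             ncbi_hit = NA_character_,
             accession = getcol("protein_id"),
             stringsAsFactors = FALSE)
}

.assign_gene_ids <- function(names, functions) {
  base <- tolower(gsub("[^A-Za-z0-9]+", "_", names))
  ids <- base
  for (nm in unique(base[duplicated(base)])) {
    idx <- which(base == nm)
    fun <- tolower(functions[idx])
    suffix <- character(length(idx))
    suffix[grepl("hexose|ketoreductase|dehydratase|epimerase|transamin|glyco",
                 fun)] <- "_sugar"
    suffix[grepl("transport", fun)] <- "_transport"
    dup_n <- 1L
    for (j in seq_along(idx)) {
      if (suffix[j] == "") {
        suffix[j] <- if (dup_n == 1L) "" else paste0("_", dup_n)
        dup_n <- dup_n + 1L
      }
    }
    # if heuristics produced identical suffixes, fall back to ordinals
    if (anyDuplicated(paste0(nm, suffix)))
      suffix <- paste0("_", seq_along(idx))
    ids[idx] <- paste0(nm, suffix)
  }
  ids
}

#' Write a cluster annotation as TSV
#'
#' Round-trips with [read_cluster_table()]: re-reading the written file
#' reproduces the object (internal gene ids are regenerated
#' deterministically).
#'
#' @param cluster a `pks_cluster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cluster, path) {
  df <- as.data.frame(cluster)[, c("name", "length_aa", "proposed_function",
                                   "ncbi_hit", "accession")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged ossamycin cluster annotation
#'
#' The 27-ORF annotation table of the ossamycin biosynthetic gene cluster of
#' *Streptomyces hygroscopicus* var. *ossamyceticus* (cluster accession
#' reported as MH763624, in one place MH7636247; both are recorded in the
#' fixture header without choosing).
#'
#' @return A `pks_cluster` of 27 gene records.
#' @export
ossamycin_cluster <- function() {
  read_cluster_table(system.file("extdata", "ossamycin_cluster.tsv",
                                 package = "pksdecode", mustWork = TRUE),
                     format = "tsv")
}

#' Ordered keyword rules for gene role classification
#'
#' First match wins; unmatched functions get role `"other"`. The role
#' vocabulary is closed (see [classify_roles()]).
#'
#' @param file optional YAML file with fields `pattern`, `role` overriding
#'   the packaged rules.
#' @return data.frame with columns `rule_id`, `pattern` (case-insensitive
#'   regex on the proposed function), `role`.
#' @export
role_rules <- function(file = NULL) {
  if (!is.null(file)) {
    cfg <- yaml::read_yaml(file)
    return(data.frame(rule_id = vapply(cfg, `[[`, "", "rule_id"),
                      pattern = vapply(cfg, `[[`, "", "pattern"),
                      role = vapply(cfg, `[[`, "", "role"),
                      stringsAsFactors = FALSE))
  }
  rules <- rbind(
    c("r_pks",        "polyketide synthase",          "modular-PKS"),
    c("r_te2",        "thioesterase",                 "thioesterase-II"),
    c("r_reg",        "regulator|luxr",               "regulator"),
    c("r_ccr",        "crotonyl-coa",                 "CCR"),
    c("r_fabh",       "ketoacyl-acp synthase iii|fabh", "FabH-like"),
    c("r_p450",       "cytochrome p450",              "cytochrome-P450"),
    c("r_spiro",      "spirocyclase",                 "spirocyclase-like"),
    c("r_sug23dh",    "2,3-dehydratase",              "sugar-2,3-dehydratase"),
    c("r_sug3kr",     "3-ketoreductase",              "sugar-3-ketoreductase"),
    c("r_sug34dh",    "3,4-dehydratase",              "sugar-3,4-dehydratase"),
    c("r_sugepi",     "epimerase",                    "sugar-epimerase"),
    c("r_sugtam",     "transaminase",                 "sugar-transaminase"),
    # primary-metabolism hydroxymethyltransferases must not hit the N-MT rule
    c("r_shmt",       "hydroxymethyltransferase",     "other"),
    c("r_sugnmt",     "methyltransferase",            "sugar-N-methyltransferase"),
    c("r_gt",         "glycosyltransferase",          "glycosyltransferase"),
    c("r_transport",  "transporter",                  "transporter"),
    c("r_hyp",        "hypothetical",                 "hypothetical"))
  data.frame(rule_id = rules[, 1], pattern = rules[, 2], role = rules[, 3],
             stringsAsFactors = FALSE)
}

.role_vocabulary <- c("modular-PKS", "thioesterase-II", "regulator", "CCR",
                      "FabH-like", "cytochrome-P450", "spirocyclase-like",
                      "sugar-2,3-dehydratase", "sugar-3-ketoreductase",
                      "sugar-3,4-dehydratase", "sugar-epimerase",
                      "sugar-transaminase", "sugar-N-methyltransferase",
                      "glycosyltransferase", "transporter", "hypothetical",
                      "other")

.sugar_roles <- c("sugar-2,3-dehydratase", "sugar-3-ketoreductase",
                  "sugar-3,4-dehydratase", "sugar-epimerase",
                  "sugar-transaminase", "sugar-N-methyltransferase")

#' Assign one biosynthetic role per gene
#'
#' Total and deterministic: every gene receives exactly one role from a
#' closed vocabulary via an ordered keyword-rule table applied to its
#' proposed function (first match wins; no match gives `"other"`). The
#' result is independent of gene order.
#'
#' @param cluster a `pks_cluster`.
#' @param rules rule table from [role_rules()].
#' @return data.frame with columns `gene_id`, `name`, `role`, `evidence`
#'   (the matching rule id, or `"no_match"`).
#' @export
classify_roles <- function(cluster, rules = role_rules()) {
  if (nrow(cluster) == 0L)
    return(data.frame(gene_id = character(), name = character(),
                      role = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  if (any(is.na(cluster$proposed_function) | cluster$proposed_function == ""))
    stop("every gene needs a non-empty proposed_function")
  if (!all(rules$role %in% .role_vocabulary))
    stop("rule table uses role(s) outside the closed vocabulary")
  role <- rep("other", nrow(cluster))
  evidence <- rep("no_match", nrow(cluster))
  fun <- tolower(cluster$proposed_function)
  for (i in seq_len(nrow(cluster))) {
    for (r in seq_len(nrow(rules))) {
      if (grepl(rules$pattern[r], fun[i])) {
        role[i] <- rules$role[r]
        evidence[i] <- rules$rule_id[r]
        break
      }
    }
  }
  data.frame(gene_id = cluster$gene_id, name = cluster$name, role = role,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Tabulate role counts
#'
#' @param roles output of [classify_roles()].
#' @return named integer vector over the closed role vocabulary, plus an
#'   aggregate `sugar-pathway` count (the six deoxyaminosugar biosynthesis
#'   roles, glycosyltransferase excluded).
#' @export
role_counts <- function(roles) {
  counts <- table(factor(roles$role, levels = .role_vocabulary))
  out <- stats::setNames(as.integer(counts), names(counts))
  c(out, `sugar-pathway` = sum(out[.sugar_roles]))
}

#' @export
print.pks_cluster <- function(x, ...) {
  cat("PKS gene cluster:", nrow(x), "genes (source:",
      attr(x, "source"), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more genes\n")
  invisible(x)
}
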