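#' Run the full cluster-decoding pipeline
#'
#' Orchestrates roles -> domains -> modules -> ordering/iteration -> product
#' -> sugar pathway into one reproducible run. Stage warnings (e.g. a
#' discordant AT) are collected, never fatal; a stage error aborts with a
#' partial report attached to the condition.
#'
#' @param cluster path to a cluster annotation table, or a `pks_cluster`.
#' @param sequences path to a protein FASTA of the PKS multienzymes, or a
#'   `pks_calls` table (e.g. the packaged call fixture); FASTA input is
#'   scanned with [scan_domains()].
#' @param target path to a target-backbone YAML, or a `pks_target`.
#' @param tailoring optional path to a tailoring-event YAML, or a list of
#'   events.
#' @param cluster_format format of the cluster file (see
#'   [read_cluster_table()]).
#' @param sugar_branch branch for [reconstruct_pathway()].
#' @param out_dir optional directory; when given, the consolidated report is
#'   written to `<out_dir>/report.json`.
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic; the seed matters when `sequences` came from the
#'   generator).
#' @return A `pks_report`: list with per-stage outputs (`cluster`, `roles`,
#'   `role_counts`, `calls`, `line`, `order`, `iteration`, `chain`,
#'   `macrolactone`, `mass`, `sugar`), `discrepancies`, `versions`, `seed`,
#'   `input_digests`.
#' @export
run_pipeline <- function(cluster, sequences, target, tailoring = NULL,
                         cluster_format = "tsv",
                         sugar_branch = "canonical",
                         out_dir = NULL, seed = NA_integer_) {
  digests <- character(0)
  digest_of <- function(x) if (is.character(x) && length(x) == 1L &&
                               file.exists(x)) unname(tools::md5sum(x))
    else NA_character_

  paths <- c(cluster = if (is.character(cluster)) cluster else NA,
             sequences = if (is.character(sequences)) sequences else NA,
             target = if (is.character(target)) target else NA)
  for (nm in names(paths))
    if (!is.na(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop("input not found: ", nm, " = ", paths[[nm]])
  digests <- vapply(paths, digest_of, "")

  if (is.character(cluster))
    cluster <- read_cluster_table(cluster, format = cluster_format)
  if (is.character(target)) target <- read_target(target)
  if (is.character(tailoring)) tailoring <- read_tailoring(tailoring)

  roles <- classify_roles(cluster)
  counts <- role_counts(roles)

  if (is.character(sequences)) {
    proteins <- read_protein_fasta(sequences)
    calls <- classify_domains(scan_domains(proteins))
  } else calls <- sequences

  line <- withCallingHandlers(
    build_modules(calls),
    warning = function(w) invokeRestart("muffleWarning"))
  order <- order_multienzymes(line, target)
  iteration <- attr(order, "iteration")
  modules <- do.call(rbind, lapply(order, function(p)
    line$modules[line$modules$protein == p & !line$modules$malformed, ,
                 drop = FALSE]))

  chain <- assemble_chain(line$loading, iteration, modules, target)
  mac <- macrolactonize(chain, target$cyclization_carbon)
  sugar <- reconstruct_pathway(roles, branch = sugar_branch)
  if (!is.null(tailoring))
    mac <- apply_tailoring(mac, tailoring, sugar = residue_formula(sugar))
  mass <- compute_mass(mac)

  report <- structure(list(
    cluster = cluster, roles = roles, role_counts = counts,
    calls = calls, line = line,
    order = as.character(order), order_score = attr(order, "score"),
    iteration = iteration, chain = chain, macrolactone = mac, mass = mass,
    sugar = sugar,
    discrepancies = iteration$discrepancies,
    warnings = line$warnings,
    versions = list(pksdecode = as.character(utils::packageVersion("pksdecode")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    seed = seed,
    input_digests = as.list(digests)),
    class = "pks_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Serializable summary of a pipeline report
#'
#' @param report a `pks_report`.
#' @return A plain list suitable for JSON serialization.
#' @export
report_json <- function(report) {
  mac <- report$macrolactone
  list(
    n_genes = nrow(report$cluster),
    role_counts = as.list(report$role_counts[report$role_counts > 0]),
    n_extension_modules = sum(!report$line$modules$malformed),
    starter_unit = report$line$loading$starter_unit,
    protein_order = report$order,
    n_cycles = length(report$iteration$cycle_to_module),
    iterated_modules = report$iteration$iterated_modules,
    stutter_cycles = if (!is.null(report$iteration$stutters))
      report$iteration$stutters$cycles else character(0),
    discrepancies = if (!is.null(report$discrepancies))
      report$discrepancies else list(),
    backbone_carbons = report$chain$backbone_carbon_count,
    ring_size = mac$ring_size,
    formula = format(mac$formula),
    monoisotopic_mass = report$mass$monoisotopic_mass,
    mh_plus = report$mass$mh_plus,
    sugar_branch = report$sugar$branch,
    sugar_missing_roles = report$sugar$missing_roles,
    sugar_formula = format(residue_formula(report$sugar)),
    warnings = report$warnings,
    versions = report$versions,
    seed = report$seed,
    input_digests = report$input_digests)
}

#' @export
print.pks_report <- function(x, ...) {
  cat("== pksdecode pipeline report ==\n")
  cat("Cluster:", nrow(x$cluster), "genes;",
      x$role_counts[["modular-PKS"]], "modular PKS;",
      x$role_counts[["cytochrome-P450"]], "P450;",
      x$role_counts[["sugar-pathway"]], "sugar-pathway genes\n")
  cat("Assembly line:", sum(!x$line$modules$malformed), "extension modules",
      "in order", paste(x$order, collapse = " -> "), "\n")
  cat("Cycles:", length(x$iteration$cycle_to_module))
  if (length(x$iteration$iterated_modules))
    cat("; iterated:", paste(x$iteration$iterated_modules, collapse = ", "),
        "at cycles", paste(x$iteration$stutters$cycles, collapse = "; "))
  cat("\n")
  cat("Product: ring size", x$macrolactone$ring_size, "| formula",
      format(x$macrolactone$formula), "| [M+H]+",
      sprintf("%.4f", x$mass$mh_plus), "\n")
  if (!is.null(x$discrepancies)) {
    cat("Discrepancies:\n"); print.data.frame(x$discrepancies)
  }
  invisible(x)
}
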