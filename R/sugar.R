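# dTDP-deoxyaminosugar pathway rule engine.
#
# The pathway to the glycosyl donor is modeled as an ordered list of steps,
# each tagged with a chemical transform and an elemental delta applied to the
# free-sugar (glycone) formula, starting from d-glucose. Two steps
# (dTDP-d-glucose synthase and the 4,6-dehydratase) are not encoded in the
# cluster and are emitted as "recruited elsewhere" placeholders.

.sugar_transforms <- list(
  list(transform = "nucleotidylation", role = "recruited-synthase",
       external = TRUE, delta = c(C = 0),
       substrate = "d-glucose-1-phosphate", product = "dTDP-d-glucose"),
  list(transform = "4,6-dehydration", role = "recruited-4,6-dehydratase",
       external = TRUE, delta = c(H = -2, O = -1),
       substrate = "dTDP-d-glucose",
       product = "dTDP-4-keto-6-deoxy-d-glucose"),
  list(transform = "2,3-dehydration", role = "sugar-2,3-dehydratase",
       external = FALSE, delta = c(H = -2, O = -1),
       substrate = "dTDP-4-keto-6-deoxy-d-glucose",
       product = "dTDP-3,4-diketo-2,6-dideoxy-d-hexose"),
  list(transform = "3-ketoreduction", role = "sugar-3-ketoreductase",
       external = FALSE, delta = c(H = 2),
       substrate = "dTDP-3,4-diketo-2,6-dideoxy-d-hexose",
       product = "dTDP-4-keto-2,6-dideoxy-d-glucose"),
  list(transform = "3,4-dehydration", role = "sugar-3,4-dehydratase",
       external = FALSE, delta = c(O = -1),  # dehydration + assisting reduction
       substrate = "dTDP-4-keto-2,6-dideoxy-d-glucose",
       product = "dTDP-d-cinerulose"),
  list(transform = "epimerisation", role = "sugar-epimerase",
       external = FALSE, delta = c(C = 0),
       substrate = "dTDP-d-cinerulose", product = "dTDP-l-cinerulose"),
  list(transform = "transamination", role = "sugar-transaminase",
       external = FALSE, delta = c(N = 1, H = 3, O = -1),
       substrate = "dTDP-l-cinerulose",
       product = "dTDP-4-amino-2,3,4,6-tetradeoxy-l-hexose"),
  list(transform = "N,N-dimethylation", role = "sugar-N-methyltransferase",
       external = FALSE, delta = c(C = 2, H = 4),
       substrate = "dTDP-4-amino-2,3,4,6-tetradeoxy-l-hexose",
       product = "dTDP-l-ossamine"),
  list(transform = "glycosyl transfer", role = "glycosyltransferase",
       external = FALSE, delta = c(C = 0),
       substrate = "dTDP-l-ossamine",
       product = "l-ossaminyl aglycone (C-8)"))

#' Reconstruct the deoxyaminosugar pathway from role assignments
#'
#' Emits one step per required enzymatic role, binding the cluster gene
#' assigned that role where one exists (a gene is looked up by role in the
#' [classify_roles()] output; the glycosyltransferase naming variants OssG /
#' OssGT are the same role and hence synonyms). Steps whose enzymes are
#' recruited from elsewhere in the genome (dTDP-d-glucose synthase, the
#' 4,6-dehydratase, and the reductase assisting the 3,4-dehydratase) are
#' flagged `external`. Missing roles are reported as data, not errors.
#'
#' The `early-epimerisation` branch moves epimerisation before
#' 3,4-dehydration; the intermediate formed there is labelled
#' kedarosamine-type, matching the sugar found at the equivalent position of
#' related macrolides.
#'
#' @param roles data.frame from [classify_roles()].
#' @param branch `"canonical"` or `"early-epimerisation"`.
#' @return A `pks_sugar_pathway`: list with `steps` (data.frame), `branch`,
#'   `missing_roles`.
#' @export
reconstruct_pathway <- function(roles,
                                branch = c("canonical", "early-epimerisation")) {
  branch <- match.arg(branch)
  steps <- .sugar_transforms
  if (branch == "early-epimerisation") {
    idx <- vapply(steps, `[[`, "", "transform")
    epi <- which(idx == "epimerisation")
    dh34 <- which(idx == "3,4-dehydration")
    steps <- append(steps[-epi], steps[epi], after = dh34 - 1L)
    # relabel the chain around the displaced step
    idx <- vapply(steps, `[[`, "", "transform")
    epi <- which(idx == "epimerisation")
    steps[[epi]]$substrate <- steps[[epi - 1L]]$product
    steps[[epi]]$product <- "dTDP-l-kedarosamine-type intermediate"
    for (k in (epi + 1L):length(steps)) {
      steps[[k]]$substrate <- steps[[k - 1L]]$product
      if (steps[[k]]$transform == "3,4-dehydration")
        steps[[k]]$product <- "dTDP-l-cinerulose"
    }
  }
  gene_for_role <- function(role) {
    hit <- roles$name[roles$role == role]
    if (length(hit)) hit[1] else NA_character_
  }
  rows <- lapply(seq_along(steps), function(i) {
    s <- steps[[i]]
    gene <- if (s$external) NA_character_ else gene_for_role(s$role)
    data.frame(order_index = i, transform = s$transform,
               enzyme_role = s$role, gene_id = gene,
               substrate_name = s$substrate, product_name = s$product,
               external = s$external,
               delta = format(do.call(chem_formula,
                                      as.list(s$delta[s$delta != 0]))),
               stringsAsFactors = FALSE)
  })
  steps_df <- do.call(rbind, rows)
  required <- vapply(steps, `[[`, "", "role")
  internal <- required[!vapply(steps, `[[`, TRUE, "external")]
  missing <- internal[!internal %in% roles$role]
  structure(list(steps = steps_df, branch = branch,
                 missing_roles = missing,
                 transforms = steps),
            class = "pks_sugar_pathway")
}

#' The l-ossamine pathway from the packaged ossamycin cluster
#'
#' @param branch see [reconstruct_pathway()].
#' @return A `pks_sugar_pathway`.
#' @export
ossamine_pathway <- function(branch = "canonical") {
  reconstruct_pathway(classify_roles(ossamycin_cluster()), branch = branch)
}

#' Elemental formula of the pathway's sugar (glycone)
#'
#' Applies each transform's elemental delta to d-glucose (C6H12O6) through
#' N,N-dimethylation, giving the free-sugar formula of the glycosyl donor
#' (the residue as transferred is this formula minus H2O).
#'
#' @param graph a `pks_sugar_pathway`.
#' @return A `pks_formula` (l-ossamine: C8H17NO2).
#' @export
residue_formula <- function(graph) {
  required <- c("4,6-dehydration", "2,3-dehydration", "3-ketoreduction",
                "3,4-dehydration", "epimerisation", "transamination",
                "N,N-dimethylation")
  have <- graph$steps$transform
  missing <- setdiff(required, have)
  if (length(missing))
    stop("pathway graph incomplete: missing transform(s) ",
         paste(missing, collapse = ", "))
  f <- parse_formula("C6H12O6")
  for (s in graph$transforms) {
    if (!s$transform %in% required) next
    d <- s$delta[s$delta != 0]
    if (length(d)) {
      pos <- d[d > 0]; neg <- d[d < 0]
      if (length(pos)) f <- formula_add(f, pos)
      if (length(neg)) f <- formula_delta(f, do.call(chem_formula,
                                                     as.list(-neg)))
    }
  }
  f
}

#' Graphviz DOT export of a sugar pathway
#'
#' @param graph a `pks_sugar_pathway`.
#' @return Character scalar with DOT source.
#' @export
pathway_dot <- function(graph) {
  edges <- apply(graph$steps, 1, function(s)
    sprintf('  "%s" -> "%s" [label="%s%s"];', s[["substrate_name"]],
            s[["product_name"]], s[["transform"]],
            ifelse(is.na(s[["gene_id"]]), " (recruited)",
                   paste0(" / ", s[["gene_id"]]))))
  paste(c("digraph sugar_pathway {", "  rankdir=LR;", edges, "}"),
        collapse = "\n")
}

#' @export
print.pks_sugar_pathway <- function(x, ...) {
  cat("Deoxyaminosugar pathway (", x$branch, " branch)\n", sep = "")
  print.data.frame(x$steps[, c("order_index", "transform", "gene_id",
                               "product_name", "external")])
  if (length(x$missing_roles))
    cat("Missing roles:", paste(x$missing_roles, collapse = ", "), "\n")
  invisible(x)
}
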