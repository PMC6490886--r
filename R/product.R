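# Predicted-product construction: linear chain, macrolactone, tailoring, mass.
#
# Carbon numbering follows polyketide convention: C-1 is the carboxyl /
# thioester carbon delivered by the LAST extension cycle, so cycle c of n
# contributes the backbone pair C-(2(n-c)+1) (carbonyl) and C-(2(n-c)+2)
# (alpha).  The beta-carbon processed by cycle c's KR/DH/ER is the carbonyl
# carbon of the previous unit, i.e. C-(2(n-c)+3); for cycle 1 that is the
# starter carbonyl.  Side-chain carbons (the branched C4 unit of the unusual
# alkylmalonyl extender) are numbered beyond the backbone.

#' Assemble the predicted linear polyketide chain
#'
#' Builds one chain unit per target extension cycle, using the cycle-to-module
#' assignment for provenance and the target backbone for the realized
#' chemistry (module-vs-target disagreements are already recorded as
#' discrepancies by [detect_iteration()]). Stereo labels are kept only where
#' chemically meaningful: a beta label on hydroxyl units, an alpha label on
#' substituted alpha-carbons not involved in an enoyl double bond.
#'
#' @param loading loading-module description from [build_modules()] (needs
#'   `starter_unit`, `starter_carbons`).
#' @param assignment a `pks_iteration`.
#' @param modules module data.frame in assembly-line order.
#' @param target a `pks_target`.
#' @return A `pks_chain`: list with `starter`, `units` (data.frame),
#'   `backbone_carbon_count`, `carbon_states` (state of each backbone
#'   carbonyl-position carbon), `alpha_substituents`.
#' @export
assemble_chain <- function(loading, assignment, modules, target) {
  ext <- target$extensions
  n <- nrow(ext)
  if (length(assignment$cycle_to_module) != n)
    stop("assignment covers ", length(assignment$cycle_to_module),
         " cycles but the target requires ", n)
  if (!all(assignment$cycle_to_module %in% modules$module_id))
    stop("assignment refers to module(s) absent from the module table")
  starter_c <- loading$starter_carbons
  if (is.na(starter_c)) stop("starter unit has unknown carbon count")
  backbone <- starter_c + 2L * n

  units <- vector("list", n)
  side_counter <- backbone
  for (c in seq_len(n)) {
    row <- ext[c, ]
    mod <- modules[modules$module_id == assignment$cycle_to_module[c], ,
                   drop = FALSE]
    subst <- switch(row$extender, malonyl = "H", methylmalonyl = "methyl",
                    `unusual-alkylmalonyl` = "isobutyl")
    alpha <- row$alpha_stereo
    if (is.na(alpha)) {
      alpha <- if (row$reduction == "methylene") mod$er_alpha else mod$kr_alpha
    }
    if (subst == "H" || row$reduction %in% c("enoyl", "ketone"))
      alpha <- NA_character_
    beta <- row$beta_stereo
    if (is.na(beta)) beta <- mod$kr_beta
    if (row$reduction != "hydroxyl") beta <- NA_character_
    side <- if (subst == "isobutyl") {
      s <- seq(side_counter + 1L, side_counter + 4L)
      side_counter <- side_counter + 4L
      paste(s, collapse = ",")
    } else NA_character_
    units[[c]] <- data.frame(
      cycle = c, module_id = mod$module_id, extender = row$extender,
      alpha_substituent = subst, beta_state = row$reduction,
      alpha_stereo = alpha, beta_stereo = beta,
      carbonyl_carbon = 2L * (n - c) + 1L, alpha_carbon = 2L * (n - c) + 2L,
      beta_carbon = 2L * (n - c) + 3L,
      side_carbons = side, stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, units)

  # oxidation state of every backbone carbonyl-position carbon
  states <- stats::setNames(rep(NA_character_, backbone),
                            paste0("C", seq_len(backbone)))
  states["C1"] <- "acid"
  for (c in seq_len(n)) states[paste0("C", 2L * (n - c) + 3L)] <-
    units$beta_state[c]
  structure(list(starter = list(unit = loading$starter_unit,
                                carbons = starter_c),
                 units = units, n_cycles = n,
                 backbone_carbon_count = backbone,
                 carbon_states = states),
            class = "pks_chain")
}

#' @export
print.pks_chain <- function(x, ...) {
  cat("Polyketide chain:", x$n_cycles, "extension cycles on a",
      x$starter$unit, "starter;", x$backbone_carbon_count,
      "backbone carbons\n")
  print.data.frame(x$units[, c("cycle", "module_id", "extender", "beta_state",
                               "alpha_stereo", "beta_stereo", "beta_carbon")])
  invisible(x)
}

# elemental formula of the free-acid linear chain
.chain_formula <- function(chain) {
  n <- chain$n_cycles
  f <- chem_formula(C = chain$backbone_carbon_count)
  f <- formula_add(f, c(O = 2, H = 1))          # C-1 carboxyl
  for (c in seq_len(n)) {
    u <- chain$units[c, ]
    # beta carbon contribution (the carbonyl of the previous unit)
    f <- formula_add(f, switch(u$beta_state,
                               ketone = c(O = 1),
                               hydroxyl = c(O = 1, H = 2),
                               enoyl = c(H = 1),
                               methylene = c(H = 2)))
    # alpha carbon of THIS unit: sp2 when this cycle ends enoyl
    base_h <- if (u$beta_state == "enoyl") 1L else 2L
    f <- formula_add(f, switch(u$alpha_substituent,
                               H = c(H = base_h),
                               methyl = c(H = base_h + 2L, C = 1),
                               isobutyl = c(H = base_h + 8L, C = 4)))
  }
  # starter carbons beyond the (already counted) carbonyl: CH2...CH3
  extra <- chain$starter$carbons - 1L
  if (extra > 0L) f <- formula_add(f, c(C = 0, H = 3), c(H = 2 * (extra - 1L)))
  f
}

#' Close the macrolactone
#'
#' Ring size is carbons C-1..C-site plus the ester oxygen, i.e. `site + 1`.
#' The site carbon must carry a hydroxyl in the assembled chain.
#'
#' @param chain a `pks_chain`.
#' @param site backbone carbon bearing the cyclizing hydroxyl.
#' @return A `pks_macrolactone`: list with `chain`, `site`, `ring_size`,
#'   `formula` (elemental formula of the macrolactone), `implausible`
#'   (TRUE for strained small rings), `tailoring` (empty),
#'   `hydroxylated_sites`.
#' @export
macrolactonize <- function(chain, site) {
  site <- as.integer(site)
  state <- chain$carbon_states[paste0("C", site)]
  if (is.na(state) || state != "hydroxyl")
    stop("cannot lactonize at C-", site, ": carbon state is ",
         ifelse(is.na(state), "an unsubstituted alpha position", state),
         ", not hydroxyl")
  ring <- site + 1L
  formula <- formula_delta(.chain_formula(chain), parse_formula("H2O"))
  structure(list(chain = chain, lactone_oxygen_carbon = site,
                 ring_size = ring,
                 implausible = ring < 6L,
                 formula = formula,
                 tailoring = list(),
                 hydroxylated_sites = character()),
            class = "pks_macrolactone")
}

#' Read a tailoring-event list
#'
#' @param path YAML file with an `events` list; each event has `kind`
#'   (hydroxylation, glycosylation, spiroacetal, hemiacetal), `site` (carbon
#'   label such as `"C-8"`), optional `partners`, `agent`, `convention`
#'   (spiroacetal: `"ketal"` closes the acetal with loss of water,
#'   `"annotation"` is formula-neutral).
#' @return List of tailoring events.
#' @export
read_tailoring <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$events
}

#' The packaged ossamycin tailoring events
#'
#' Four cytochrome-P450 hydroxylations (macrocycle C-4, C-8, C-10; side-chain
#' C-35 label), spiroacetal closure at the C-25 ketone onto the C-21/C-29
#' hydroxyls, side-chain hemiacetal at the C-19 ketone, and transfer of
#' l-ossamine onto the C-8 hydroxyl.
#'
#' @return List of tailoring events.
#' @export
ossamycin_tailoring <- function() {
  read_tailoring(system.file("extdata", "ossamycin_tailoring.yaml",
                             package = "pksdecode", mustWork = TRUE))
}

.site_carbon <- function(site) {
  m <- regmatches(site, regexpr("^C-?([0-9]+)$", site))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(gsub("[^0-9]", "", m))
}

#' Apply post-PKS tailoring events
#'
#' Events are applied in list order and their formula deltas accumulated.
#' Glycosylation at a site requires a prior hydroxylation event at that site
#' or a chain hydroxyl on that backbone carbon (the C-8 hydroxyl/ossamine
#' dependency). Spiroacetal closure requires a ketone at the event site and,
#' under the `"ketal"` convention, subtracts one water.
#'
#' @param mac a `pks_macrolactone`.
#' @param events list of tailoring events ([read_tailoring()]).
#' @param sugar elemental formula of the transferred sugar as FREE sugar
#'   (default: l-ossamine from the packaged pathway, see [residue_formula()]);
#'   glycosylation adds `sugar - H2O`.
#' @return The updated `pks_macrolactone`.
#' @export
apply_tailoring <- function(mac, events,
                            sugar = residue_formula(ossamine_pathway())) {
  for (ev in events) {
    kind <- ev$kind
    if (is.null(kind) ||
        !kind %in% c("hydroxylation", "glycosylation", "spiroacetal",
                     "hemiacetal"))
      stop("unknown tailoring event kind: ",
           if (is.null(kind)) "<missing>" else kind)
    site <- ev$site
    carbon <- .site_carbon(site)
    if (kind == "hydroxylation") {
      mac$formula <- formula_add(mac$formula, c(O = 1))
      mac$hydroxylated_sites <- c(mac$hydroxylated_sites, site)
    } else if (kind == "glycosylation") {
      chain_oh <- !is.na(carbon) &&
        identical(unname(mac$chain$carbon_states[paste0("C", carbon)]),
                  "hydroxyl")
      if (!(site %in% mac$hydroxylated_sites) && !chain_oh)
        stop("glycosylation at ", site, " requires a prior hydroxylation ",
             "at that site, without which glycosyl transfer cannot occur")
      mac$formula <- formula_add(mac$formula,
                                 formula_delta(sugar, parse_formula("H2O")))
    } else if (kind == "spiroacetal") {
      if (!is.na(carbon)) {
        st <- mac$chain$carbon_states[paste0("C", carbon)]
        if (is.na(st) || st != "ketone")
          stop("spiroacetal at ", site, " requires a ketone; found ",
               ifelse(is.na(st), "an alpha carbon", st))
      }
      convention <- if (is.null(ev$convention)) "annotation" else ev$convention
      if (convention == "ketal")
        mac$formula <- formula_delta(mac$formula, parse_formula("H2O"))
    } else if (kind == "hemiacetal") {
      # ketone + hydroxyl -> cyclic hemiketal: connectivity only
    }
    mac$tailoring[[length(mac$tailoring) + 1L]] <- ev
  }
  mac
}

#' Molecular formula and monoisotopic mass of a (tailored) macrolactone
#'
#' @param mac a `pks_macrolactone`.
#' @return A list: `formula` (a `pks_formula`), `monoisotopic_mass` (Da) and
#'   `mh_plus` (the \[M+H\]+ ion, Da).
#' @export
compute_mass <- function(mac) {
  if (any(is.na(mac$chain$units$beta_state)))
    stop("unresolved beta-state in chain unit(s): formula undetermined")
  mass <- monoisotopic_mass(mac$formula)
  list(formula = mac$formula,
       monoisotopic_mass = round(mass, 4),
       mh_plus = round(mass + .proton_mass, 4))
}

#' @export
print.pks_macrolactone <- function(x, ...) {
  cat("Macrolactone: ring size", x$ring_size, "(lactone O on C-",
      x$lactone_oxygen_carbon, ")",
      if (x$implausible) "[implausibly small ring]", "\n")
  cat("Formula:", format(x$formula),
      sprintf("| monoisotopic %.4f Da | [M+H]+ %.4f\n",
              monoisotopic_mass(x$formula),
              monoisotopic_mass(x$formula) + .proton_mass))
  if (length(x$tailoring))
    cat("Tailoring:", paste(vapply(x$tailoring, function(e)
      paste0(e$kind, "@", e$site), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Drop one extension cycle from a target backbone
#'
#' Utility for comparing iterated and non-iterated assembly lines: removes
#' the given cycle, renumbers the remaining cycles, and moves the
#' macrolactonization site to the homologous hydroxyl (the one produced by
#' the same, renumbered cycle).
#'
#' @param target a `pks_target`.
#' @param cycle cycle index to remove.
#' @return A new `pks_target` with one fewer extension.
#' @export
drop_cycle <- function(target, cycle) {
  ext <- target$extensions
  n <- nrow(ext)
  stopifnot(cycle >= 1L, cycle <= n)
  # which cycle produced the lactone hydroxyl (its beta carbon = site)
  site_cycle <- as.integer(n - (target$cyclization_carbon - 3L) / 2L)
  ext <- ext[-cycle, , drop = FALSE]
  ext$cycle <- seq_len(nrow(ext))
  if (site_cycle > cycle) site_cycle <- site_cycle - 1L
  new_site <- 2L * (nrow(ext) - site_cycle) + 3L
  structure(list(name = paste0(target$name, " (cycle ", cycle, " removed)"),
                 starter = target$starter,
                 cyclization_carbon = new_site,
                 extensions = ext),
            class = "pks_target")
}
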