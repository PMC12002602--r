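#' @keywords internal
"_PACKAGE"

#' Default compartment registry
#'
#' Three-compartment layout typical of filamentous-fungal reconstructions:
#' extracellular space, cytosol and mitochondrion, keyed by the id suffixes
#' used on metabolite identifiers (`_e`, `_c`, `_m`).
#'
#' @return Named character vector mapping compartment id to label.
#' @export
default_compartments <- function() {
  c(e = "extracellular", c = "cytosol", m = "mitochondrion")
}

#' Construct a metabolite
#'
#' @param id Unique metabolite identifier (convention: `name_<compartment>`).
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Compartment id; must be registered in the model that
#'   receives this metabolite. If `NULL`, inferred from a trailing
#'   `_<compartment>` suffix on `id`.
#' @param formula Optional named numeric vector of element counts.
#' @param annotations Optional named list of database -> identifier entries
#'   (e.g. BioCyc, KEGG, ChEBI).
#' @return An object of class `of_metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = NULL, formula = NULL,
                       annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(compartment)) {
    m <- regmatches(id, regexpr("_([A-Za-z]+)$", id))
    if (length(m) == 0L) {
      stop("metabolite '", id, "': no compartment given and none inferrable from id")
    }
    compartment <- sub("^_", "", m)
  }
  structure(
    list(id = id, name = name, compartment = compartment,
         formula = formula, annotations = annotations),
    class = "of_metabolite"
  )
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative = consumed, positive =
#' produced. Flux bounds are in mmol per gDW per hour; the default span
#' (-1000, 1000) is the community convention for an unconstrained reversible
#' reaction.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds (mmol/gDW/h).
#' @param name Human-readable name.
#' @param gpr Gene-protein-reaction rule as a boolean expression string over
#'   gene ids (`and`/`or`, parentheses); `""` means no gene association.
#' @param kind One of `internal`, `transport`, `exchange`, `demand`,
#'   `biomass`; inferred from the id prefix (`EX_`, `DM_`) and structure when
#'   `NULL`.
#' @param annotations Named list of database -> identifier entries.
#' @return An object of class `of_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000, upper_bound = 1000,
                     name = id, gpr = "", kind = NULL, annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "': stoichiometry must be non-empty")
  }
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a named numeric vector")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("reaction '", id, "': duplicate metabolite in stoichiometry")
  }
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      lower_bound > upper_bound) {
    stop("reaction '", id, "': requires lower_bound <= upper_bound")
  }
  if (is.null(kind)) {
    kind <- if (startsWith(id, "EX_")) "exchange"
            else if (startsWith(id, "DM_")) "demand"
            else if (grepl("biomass", id, ignore.case = TRUE)) "biomass"
            else "internal"
  }
  kind <- match.arg(kind, c("internal", "transport", "exchange", "demand", "biomass"))
  if (kind %in% c("exchange", "demand") && length(stoichiometry) != 1L) {
    stop("reaction '", id, "': ", kind, " reactions must touch exactly one metabolite")
  }
  structure(
    list(id = id, name = name, stoichiometry = stoichiometry,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         gpr = if (is.null(gpr) || is.na(gpr)) "" else gpr,
         kind = kind, annotations = annotations),
    class = "of_reaction"
  )
}

#' Construct a gene
#' @param id Unique gene identifier.
#' @param name Optional gene name.
#' @return An object of class `of_gene`.
#' @export
gene <- function(id, name = NA_character_) {
  structure(list(id = id, name = name), class = "of_gene")
}

#' Assemble a metabolic model
#'
#' Metabolites absent from `metabolites` but referenced by a reaction are
#' created automatically (compartment inferred from the id suffix); genes are
#' completed from the GPR rules. Duplicate reaction or metabolite ids are a
#' hard error: silent shadowing would corrupt downstream flux maps.
#'
#' @param reactions List of [reaction()] objects.
#' @param metabolites Optional list of [metabolite()] objects.
#' @param genes Optional list of [gene()] objects.
#' @param compartments Named character registry, id -> label.
#' @param objective Reaction id of the objective (typically the biomass
#'   reaction).
#' @param id Model identifier.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites = list(), genes = list(),
                            compartments = default_compartments(),
                            objective, id = "model") {
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  met_ids <- vapply(metabolites, `[[`, "", "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  # auto-create metabolites referenced only in stoichiometries
  referenced <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  for (mid in setdiff(referenced, met_ids)) {
    metabolites <- c(metabolites, list(metabolite(mid)))
  }
  met_ids <- vapply(metabolites, `[[`, "", "id")
  bad_comp <- setdiff(vapply(metabolites, `[[`, "", "compartment"), names(compartments))
  if (length(bad_comp) > 0L) {
    stop("unregistered compartment(s): ", paste(bad_comp, collapse = ", "))
  }
  # complete gene list from GPRs
  gene_ids <- vapply(genes, `[[`, "", "id")
  gpr_refs <- unique(unlist(lapply(reactions, function(r) gpr_genes(parse_gpr(r$gpr)))))
  for (gid in setdiff(gpr_refs, gene_ids)) {
    genes <- c(genes, list(gene(gid)))
  }
  if (!missing(objective) && !objective %in% rxn_ids) {
    stop("objective reaction '", objective, "' not in model")
  }
  if (missing(objective)) {
    bm <- rxn_ids[vapply(reactions, function(r) r$kind == "biomass", TRUE)]
    if (length(bm) == 0L) stop("no objective given and no biomass reaction found")
    objective <- bm[[1L]]
  }
  names(reactions) <- rxn_ids
  names(metabolites) <- met_ids
  names(genes) <- vapply(genes, `[[`, "", "id")
  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = genes, compartments = compartments, objective = objective),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, %d genes>\n",
              x$id, length(x$metabolites), length(x$reactions), length(x$genes)))
  cat("  compartments:", paste(sprintf("%s (%s)", names(x$compartments),
                                       x$compartments), collapse = ", "), "\n")
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Reaction / metabolite identifiers of a model
#' @param model A `metabolic_model`.
#' @return Character vector of ids in model order.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) names(model$metabolites)

#' Reaction table view of a model
#'
#' @param model A `metabolic_model`.
#' @return A data.frame with one row per reaction: id, name, kind, bounds,
#'   gpr and a human-readable equation string.
#' @export
reaction_table <- function(model) {
  data.frame(
    id = reaction_ids(model),
    name = vapply(model$reactions, `[[`, "", "name"),
    kind = vapply(model$reactions, `[[`, "", "kind"),
    lower_bound = vapply(model$reactions, `[[`, 0, "lower_bound"),
    upper_bound = vapply(model$reactions, `[[`, 0, "upper_bound"),
    gpr = vapply(model$reactions, `[[`, "", "gpr"),
    equation = vapply(model$reactions, format_equation, ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

format_equation <- function(rxn) {
  s <- rxn$stoichiometry
  fmt <- function(v) {
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  }
  lhs <- s[s < 0]; rhs <- s[s > 0]
  arrow <- if (rxn$lower_bound < 0 && rxn$upper_bound > 0) "<->" else "->"
  paste(fmt(lhs), arrow, fmt(rhs))
}

#' Build the stoichiometric matrix S
#'
#' Rows are metabolites, columns reactions; entry (i, j) is the signed
#' stoichiometric coefficient of metabolite i in reaction j. This is the `S`
#' of the steady-state constraint `S v = 0` underlying all flux balance
#' computations.
#'
#' @param model A `metabolic_model`.
#' @return A sparse `Matrix::dgCMatrix` with metabolite ids as rownames and
#'   reaction ids as colnames.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- metabolite_ids(model)
  rids <- reaction_ids(model)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoichiometry
    idx <- match(names(s), mids)
    if (anyNA(idx)) {
      stop("reaction '", rids[k], "': unresolved metabolite id(s): ",
           paste(names(s)[is.na(idx)], collapse = ", "))
    }
    i <- c(i, idx); j <- c(j, rep.int(k, length(s))); x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

# dense S for the LP core; avoids sparse-matrix dispatch on hot paths
dense_stoich <- function(model) {
  mids <- metabolite_ids(model)
  rids <- reaction_ids(model)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoichiometry
    idx <- match(names(s), mids)
    if (anyNA(idx)) {
      stop("reaction '", rids[k], "': unresolved metabolite id(s): ",
           paste(names(s)[is.na(idx)], collapse = ", "))
    }
    S[idx, k] <- unname(s)
  }
  S
}

#' Modify reaction bounds
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param lower,upper New bounds; `NULL` leaves the bound unchanged.
#' @return The modified model (the input is untouched).
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  if (!id %in% reaction_ids(model)) stop("no reaction '", id, "' in model")
  r <- model$reactions[[id]]
  if (!is.null(lower)) r$lower_bound <- as.numeric(lower)
  if (!is.null(upper)) r$upper_bound <- as.numeric(upper)
  if (r$lower_bound > r$upper_bound) {
    stop("reaction '", id, "': lower bound exceeds upper bound")
  }
  model$reactions[[id]] <- r
  model
}

#' Add a reaction to a model
#'
#' @param model A `metabolic_model`.
#' @param rxn A [reaction()] object.
#' @return The extended model; new metabolites and genes are registered.
#' @export
add_reaction <- function(model, rxn) {
  metabolic_model(
    reactions = c(unname(model$reactions), list(rxn)),
    metabolites = unname(model$metabolites),
    genes = unname(model$genes),
    compartments = model$compartments,
    objective = model$objective,
    id = model$id
  )
}
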