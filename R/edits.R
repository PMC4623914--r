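# Declarative network edits: the species-specific surgery a reconstruction
# needs (adding a cytosolic malic enzyme, closing an ethanol exporter,
# completing the mannitol cycle, swapping the biomass equation) expressed as
# a list of directives so that edits are reviewable and replayable from a
# YAML/JSON file.

#' Edit directive constructors
#'
#' Each constructor returns one directive for [apply_edits()]. Available
#' actions: `add_metabolite`, `add_reaction`, `remove_reaction`,
#' `set_bounds`, `set_objective`, `add_coupling`.
#'
#' @param id,name,compartment,formula,charge metabolite fields.
#' @return a directive (named list with an `action` field).
#' @export
edit_add_metabolite <- function(id, name = id, compartment, formula = NA,
                                charge = NA) {
  list(action = "add_metabolite", id = id, name = name,
       compartment = compartment, formula = formula, charge = charge)
}

#' @rdname edit_add_metabolite
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lb,ub flux bounds in mmol/gDW/h.
#' @param gene_rule boolean gene association string.
#' @param subsystem subsystem label.
#' @param pseudo flag biomass/maintenance/demand pseudo-reactions (exempt
#'   from elemental balancing).
#' @export
edit_add_reaction <- function(id, stoichiometry, lb = -1000, ub = 1000,
                              name = id, gene_rule = "", subsystem = "",
                              pseudo = FALSE) {
  list(action = "add_reaction", id = id, name = name,
       stoichiometry = stoichiometry, lb = lb, ub = ub,
       gene_rule = gene_rule, subsystem = subsystem, pseudo = pseudo)
}

#' @rdname edit_add_metabolite
#' @param drop_orphans drop metabolites left without any reaction.
#' @export
edit_remove_reaction <- function(id, drop_orphans = FALSE) {
  list(action = "remove_reaction", id = id, drop_orphans = drop_orphans)
}

#' @rdname edit_add_metabolite
#' @export
edit_set_bounds <- function(id, lb = NULL, ub = NULL) {
  list(action = "set_bounds", id = id, lb = lb, ub = ub)
}

#' @rdname edit_add_metabolite
#' @param weights named numeric vector reaction id -> objective weight;
#'   replaces the whole objective.
#' @export
edit_set_objective <- function(weights) {
  list(action = "set_objective", weights = weights)
}

#' @rdname edit_add_metabolite
#' @param target,source reaction ids; `ratio` enforces
#'   `v[target] == ratio * v[source]`.
#' @param ratio coupling ratio.
#' @export
edit_add_coupling <- function(target, source, ratio) {
  list(action = "add_coupling", target = target, source = source,
       ratio = ratio)
}

#' Apply a list of edit directives to a model
#'
#' Returns a new model; the input is never modified. Enzymatic
#' `add_reaction` directives are checked for elemental balance when every
#' participant carries a formula (`balance = "error"` rejects imbalance,
#' `"warn"` reports it, `"none"` skips the check — use the advisory modes
#' for reconstructions with incomplete formula annotation).
#'
#' @param model a [metabolic_model].
#' @param edits list of directives from the `edit_*` constructors (a single
#'   directive is also accepted), or a path readable by [read_edits()].
#' @param balance one of `"error"`, `"warn"`, `"none"`.
#' @param balance_elements elements to balance (default carbon only, the
#'   element lumped models track reliably); `NULL` checks all.
#' @return the edited [metabolic_model].
#' @export
apply_edits <- function(model, edits, balance = "error",
                        balance_elements = "C") {
  balance <- match.arg(balance, c("error", "warn", "none"))
  if (is.character(edits) && length(edits) == 1) edits <- read_edits(edits)
  if (!is.null(edits$action)) edits <- list(edits)
  met <- model$metabolites
  rxn <- model$reactions
  S <- model$S
  compartments <- model$compartments
  couplings <- model$couplings

  for (ed in edits) {
    switch(
      ed$action,
      add_metabolite = {
        if (ed$id %in% met$id) stop("metabolite already exists: ", ed$id)
        if (!ed$compartment %in% compartments$id)
          stop("unknown compartment: ", ed$compartment)
        met <- rbind(met, data.frame(
          id = ed$id, name = ed$name, compartment = ed$compartment,
          formula = if (is.null(ed$formula)) NA_character_ else as.character(ed$formula),
          charge = if (is.null(ed$charge)) NA_integer_ else as.integer(ed$charge),
          boundary = FALSE, stringsAsFactors = FALSE))
        S <- rbind(S, Matrix::Matrix(0, 1, ncol(S), sparse = TRUE))
        rownames(S) <- met$id
      },
      add_reaction = {
        if (ed$id %in% rxn$id) stop("reaction already exists: ", ed$id)
        sto <- unlist(ed$stoichiometry)
        miss <- setdiff(names(sto), met$id)
        if (length(miss)) stop("unknown metabolite id: ", miss[1])
        col <- Matrix::Matrix(0, nrow(S), 1, sparse = TRUE)
        col[match(names(sto), met$id), 1] <- as.numeric(sto)
        S <- cbind(S, col)
        rxn <- rbind(rxn, data.frame(
          id = ed$id, name = ed$name, lb = ed$lb, ub = ed$ub,
          gene_rule = ed$gene_rule, subsystem = ed$subsystem,
          objective = 0, pseudo = isTRUE(ed$pseudo),
          stringsAsFactors = FALSE))
        colnames(S) <- rxn$id
        if (balance != "none" && !isTRUE(ed$pseudo)) {
          tmp <- .as_model_parts(model, met, rxn, S, compartments, couplings)
          kinds <- reaction_kinds(tmp)
          j <- nrow(rxn)
          if (kinds[j] == "enzymatic") {
            net <- reaction_imbalance(tmp, ed$id, balance_elements)
            if (!is.null(net) && any(abs(net) > 1e-6)) {
              bad <- net[abs(net) > 1e-6]
              msg <- paste0("reaction ", ed$id, " is elementally unbalanced: ",
                            paste(sprintf("%s %+g", names(bad), bad),
                                  collapse = ", "))
              if (balance == "error") stop(msg) else warning(msg)
            }
          }
        }
      },
      remove_reaction = {
        j <- match(ed$id, rxn$id)
        if (is.na(j)) stop("unknown reaction id: ", ed$id)
        rxn <- rxn[-j, , drop = FALSE]
        S <- S[, -j, drop = FALSE]
        couplings <- couplings[couplings$target != ed$id &
                                 couplings$source != ed$id, , drop = FALSE]
        if (isTRUE(ed$drop_orphans)) {
          keep <- Matrix::rowSums(S != 0) > 0
          met <- met[keep, , drop = FALSE]
          S <- S[keep, , drop = FALSE]
        }
      },
      set_bounds = {
        j <- match(ed$id, rxn$id)
        if (is.na(j)) stop("unknown reaction id: ", ed$id)
        if (!is.null(ed$lb)) rxn$lb[j] <- ed$lb
        if (!is.null(ed$ub)) rxn$ub[j] <- ed$ub
      },
      set_objective = {
        wt <- unlist(ed$weights)
        miss <- setdiff(names(wt), rxn$id)
        if (length(miss)) stop("unknown reaction id: ", miss[1])
        rxn$objective <- 0
        rxn$objective[match(names(wt), rxn$id)] <- as.numeric(wt)
      },
      add_coupling = {
        miss <- setdiff(c(ed$target, ed$source), rxn$id)
        if (length(miss)) stop("unknown reaction id: ", miss[1])
        couplings <- rbind(couplings, data.frame(
          target = ed$target, source = ed$source, ratio = ed$ratio,
          stringsAsFactors = FALSE))
      },
      stop("unknown edit action: ", ed$action))
  }
  .as_model_parts(model, met, rxn, S, compartments, couplings)
}

.as_model_parts <- function(model, met, rxn, S, compartments, couplings) {
  rownames(met) <- NULL; rownames(rxn) <- NULL
  out <- model
  out$metabolites <- met
  out$reactions <- rxn
  out$S <- S
  dimnames(out$S) <- list(met$id, rxn$id)
  out$compartments <- compartments
  out$couplings <- couplings
  out$genes <- sort(unique(unlist(lapply(rxn$gene_rule, gpr_genes))))
  validate_model(out)
  out
}

#' Read edit directives from a YAML or JSON file
#'
#' The file holds a list of directives, each a mapping with an `action`
#' field mirroring the `edit_*` constructors; `stoichiometry` and `weights`
#' are mappings from id to coefficient.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list of directives for [apply_edits()].
#' @export
read_edits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  lapply(raw, function(ed) {
    stopifnot(!is.null(ed$action))
    defaults <- switch(ed$action,
      add_reaction = list(lb = -1000, ub = 1000, name = ed$id,
                          gene_rule = "", subsystem = "", pseudo = FALSE),
      add_metabolite = list(name = ed$id, formula = NA, charge = NA),
      remove_reaction = list(drop_orphans = FALSE),
      list())
    modifyList(defaults, ed)
  })
}
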