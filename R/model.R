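# The metabolic_model container: stoichiometry, bounds, gene rules,
# compartments and flux couplings, in the style of COBRA-era toolboxes.

#' Construct a metabolic model
#'
#' The central data structure of the package. The stoichiometric matrix `S`
#' has one row per metabolite (boundary species included in the table but
#' excluded from the steady-state constraint) and one column per reaction;
#' reversibility is encoded purely by the bounds.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`, `boundary`.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `gene_rule`, `subsystem`, `objective`, `pseudo`.
#' @param S numeric or `Matrix` sparse matrix, metabolites x reactions.
#' @param compartments data.frame with columns `id`, `name`, `outside`.
#' @param external id of the external (extracellular) compartment.
#' @param couplings data.frame with columns `target`, `source`, `ratio`;
#'   each row enforces `v[target] == ratio * v[source]` in every solve.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S,
                            compartments, external,
                            couplings = empty_couplings()) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(metabolites$id, reactions$id)
  model <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions,
         S = S,
         genes = sort(unique(unlist(lapply(reactions$gene_rule, gpr_genes)))),
         compartments = compartments,
         external = external,
         couplings = couplings),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' @export
empty_couplings <- function() {
  data.frame(target = character(), source = character(),
             ratio = numeric(), stringsAsFactors = FALSE)
}

#' Validate model invariants
#'
#' Checks id uniqueness, compartment references, bound ordering, matrix
#' shape, objective and coupling references. Called by every constructor
#' and after edits; errors name the first offending element.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id))
    stop("duplicated metabolite id: ", met$id[duplicated(met$id)][1])
  if (anyDuplicated(rxn$id))
    stop("duplicated reaction id: ", rxn$id[duplicated(rxn$id)][1])
  bad <- setdiff(met$compartment, model$compartments$id)
  if (length(bad))
    stop("metabolite compartment not in model: ", bad[1])
  if (nrow(model$S) != nrow(met) || ncol(model$S) != nrow(rxn))
    stop("stoichiometric matrix shape does not match metabolite/reaction tables")
  if (any(rxn$lb > rxn$ub))
    stop("lower bound exceeds upper bound for reaction: ",
         rxn$id[which(rxn$lb > rxn$ub)[1]])
  if (!all(is.finite(rxn$lb)) || !all(is.finite(rxn$ub)))
    stop("non-finite bounds; use +/-1000 for unconstrained reactions")
  cp <- model$couplings
  if (nrow(cp)) {
    miss <- setdiff(c(cp$target, cp$source), rxn$id)
    if (length(miss)) stop("coupling references unknown reaction: ", miss[1])
    if (any(!is.finite(cp$ratio))) stop("coupling ratio must be finite")
    if (any(cp$target == cp$source))
      stop("cannot couple a reaction to itself: ",
           cp$target[cp$target == cp$source][1])
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model", sQuote(x$id), "\n")
  cat("  reactions:   ", nrow(x$reactions), "\n")
  cat("  metabolites: ", nrow(x$metabolites),
      sprintf(" (%d boundary)", sum(x$metabolites$boundary)), "\n")
  cat("  genes:       ", length(x$genes), "\n")
  cat("  compartments:", nrow(x$compartments),
      sprintf(" (external: %s)", x$external), "\n")
  if (nrow(x$couplings)) cat("  couplings:   ", nrow(x$couplings), "\n")
  obj <- x$reactions$id[x$reactions$objective != 0]
  if (length(obj)) cat("  objective:   ", paste(obj, collapse = ", "), "\n")
  invisible(x)
}

# strip a trailing compartment tag from a metabolite id: "glc_D_c" or
# "glc_D[c]" -> "glc_D"; used to decide whether a reaction changes chemistry
.strip_compartment <- function(ids, compartments) {
  pat1 <- paste0("\\[(", paste(compartments, collapse = "|"), ")\\]$")
  pat2 <- paste0("_(", paste(compartments, collapse = "|"), ")$")
  gsub(pat2, "", gsub(pat1, "", ids))
}

#' Classify reactions as exchange / transport / enzymatic / pseudo
#'
#' `exchange`: touches exactly one non-boundary species and that species
#' lives in the external compartment, or the reaction involves a
#' boundary-condition species. `transport`: participants span at least two
#' compartments with no change in chemistry (same formulas, or the same
#' compartment-stripped species ids, on both sides). Biomass, maintenance
#' and demand/sink reactions are `pseudo`; everything else `enzymatic`.
#'
#' @param model a `metabolic_model`.
#' @return factor of length `nrow(model$reactions)`.
#' @export
reaction_kinds <- function(model) {
  S <- model$S
  met <- model$metabolites
  comps <- model$compartments$id
  n <- ncol(S)
  kind <- character(n)
  base_id <- .strip_compartment(met$id, comps)
  for (j in seq_len(n)) {
    if (isTRUE(model$reactions$pseudo[j])) { kind[j] <- "pseudo"; next }
    part <- which(S[, j] != 0)
    nb <- part[!met$boundary[part]]
    has_boundary <- length(part) > length(nb)
    if (length(nb) == 1 &&
        (has_boundary || met$compartment[nb] == model$external)) {
      kind[j] <- "exchange"; next
    }
    comp_span <- unique(met$compartment[part])
    if (length(comp_span) >= 2) {
      coef <- S[part, j]
      lhs <- part[coef < 0]; rhs <- part[coef > 0]
      f <- met$formula[part]
      chem_equal <- if (!anyNA(f) && all(nzchar(f))) {
        length(lhs) && length(rhs) &&
          identical(sort(met$formula[lhs]), sort(met$formula[rhs]))
      } else {
        length(lhs) && length(rhs) &&
          identical(sort(base_id[lhs]), sort(base_id[rhs]))
      }
      if (chem_equal) { kind[j] <- "transport"; next }
    }
    kind[j] <- "enzymatic"
  }
  factor(kind, levels = c("exchange", "transport", "enzymatic", "pseudo"))
}

#' Summarize a metabolic model
#'
#' Counts of reactions by kind (with fractions of the reaction total), of
#' metabolites, genes, compartments and subsystems, plus the split of
#' enzymatic reactions with and without a gene association.
#'
#' @param model a `metabolic_model`.
#' @return object of class `model_summary`.
#' @export
summarize_model <- function(model) {
  kinds <- reaction_kinds(model)
  n_rxn <- nrow(model$reactions)
  enz <- kinds == "enzymatic"
  has_gpr <- vapply(model$reactions$gene_rule,
                    function(r) length(gpr_genes(r)) > 0, logical(1))
  frac <- function(k) if (n_rxn) unname(k) / n_rxn else 0
  subsys <- unique(model$reactions$subsystem)
  subsys <- subsys[!is.na(subsys) & nzchar(subsys)]
  out <- list(
    n_reactions = n_rxn,
    n_metabolites = sum(!model$metabolites$boundary),
    n_genes = length(model$genes),
    n_compartments = nrow(model$compartments),
    n_exchange = sum(kinds == "exchange"),
    n_transport = sum(kinds == "transport"),
    n_enzymatic_with_gpr = sum(enz & has_gpr),
    n_enzymatic_without_gpr = sum(enz & !has_gpr),
    n_pseudo = sum(kinds == "pseudo"),
    frac_exchange = frac(sum(kinds == "exchange")),
    frac_transport = frac(sum(kinds == "transport")),
    frac_enzymatic_with_gpr = frac(sum(enz & has_gpr)),
    frac_enzymatic_without_gpr = frac(sum(enz & !has_gpr)),
    n_subsystems = length(subsys))
  structure(out, class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("reactions:    %d\n", x$n_reactions))
  cat(sprintf("  exchange:   %d (%.1f %%)\n", x$n_exchange,
              100 * x$frac_exchange))
  cat(sprintf("  transport:  %d (%.1f %%)\n", x$n_transport,
              100 * x$frac_transport))
  cat(sprintf("  enzymatic:  %d with GPR (%.1f %%), %d without (%.1f %%)\n",
              x$n_enzymatic_with_gpr, 100 * x$frac_enzymatic_with_gpr,
              x$n_enzymatic_without_gpr, 100 * x$frac_enzymatic_without_gpr))
  cat(sprintf("  pseudo:     %d\n", x$n_pseudo))
  cat(sprintf("metabolites:  %d\n", x$n_metabolites))
  cat(sprintf("genes:        %d\n", x$n_genes))
  cat(sprintf("compartments: %d\n", x$n_compartments))
  cat(sprintf("subsystems:   %d\n", x$n_subsystems))
  invisible(x)
}

# ---- elemental formulas ----------------------------------------------------

#' Parse an elemental formula into element counts
#'
#' @param formula e.g. `"C6H12O6"`; `NA` or `""` give an empty vector.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(setNames(numeric(), character()))
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", sQuote(formula))
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- suppressWarnings(as.numeric(sub("^[A-Z][a-z]?", "", parts)))
  ct[is.na(ct)] <- 1
  tot <- tapply(ct, el, sum)
  setNames(as.numeric(tot[unique(el)]), unique(el))
}

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                  P = 30.974, S = 32.06, Na = 22.99, K = 39.098,
                  Fe = 55.845, Mg = 24.305)

#' Molecular weight from an elemental formula
#'
#' @param formula elemental formula string.
#' @return weight in g/mol, or `NA` if the formula is absent/unparseable.
#' @export
formula_weight <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  counts <- tryCatch(parse_formula(formula), error = function(e) NULL)
  if (is.null(counts)) return(NA_real_)
  if (!all(names(counts) %in% names(.ATOMIC_MASS))) return(NA_real_)
  sum(counts * .ATOMIC_MASS[names(counts)])
}

#' Elemental imbalance of a reaction
#'
#' Sums `coefficient * formula` over all participants. Only the requested
#' elements are checked; participants without a formula make the check
#' unavailable (`NULL`). Lumped models that track carbon skeletons should
#' check `elements = "C"` (the default used by the synthetic generator).
#'
#' @param model a `metabolic_model`.
#' @param reaction reaction id.
#' @param elements elements to balance, or `NULL` for all present.
#' @return named vector of net element production (zero when balanced), or
#'   `NULL` when any participant lacks a formula.
#' @export
reaction_imbalance <- function(model, reaction, elements = NULL) {
  j <- match(reaction, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  part <- which(model$S[, j] != 0)
  f <- model$metabolites$formula[part]
  if (anyNA(f) || any(!nzchar(f))) return(NULL)
  counts <- lapply(f, parse_formula)
  els <- unique(unlist(lapply(counts, names)))
  if (!is.null(elements)) els <- intersect(els, elements)
  if (!length(els)) return(setNames(numeric(), character()))
  net <- setNames(numeric(length(els)), els)
  coef <- model$S[part, j]
  for (k in seq_along(part)) {
    ck <- counts[[k]][els]
    ck[is.na(ck)] <- 0
    net <- net + coef[k] * ck
  }
  net
}
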