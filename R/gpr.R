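# Gene-protein-reaction (GPR) boolean rules: "(g1 and g2) or g3".

.gpr_tokens <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  tok <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  tok[nzchar(tok)]
}

#' Extract gene identifiers from a GPR rule
#'
#' @param rule a boolean gene association string; `""` or `NA` yield no genes.
#' @return character vector of unique gene ids.
#' @export
gpr_genes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  tok <- .gpr_tokens(rule)
  unique(tok[!tolower(tok) %in% c("and", "or", "(", ")")])
}

#' Evaluate a GPR rule under gene knockouts
#'
#' A reaction is available when its rule evaluates `TRUE` with every knocked
#' out gene set to `FALSE` and every other gene `TRUE`. Empty rules are
#' always available (spontaneous / orphan reactions).
#'
#' @param rule gene association string (AND/OR over gene ids, parentheses).
#' @param knockouts character vector of deleted gene ids.
#' @return logical scalar.
#' @export
gpr_eval <- function(rule, knockouts = character()) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(TRUE)
  tok <- .gpr_tokens(rule)
  expr <- vapply(tok, function(t) {
    lt <- tolower(t)
    if (lt == "and") "&&"
    else if (lt == "or") "||"
    else if (t %in% c("(", ")")) t
    else if (t %in% knockouts) "FALSE" else "TRUE"
  }, character(1))
  txt <- paste(expr, collapse = " ")
  out <- tryCatch(eval(parse(text = txt)[[1]], envir = baseenv()),
                  error = function(e) NA)
  if (is.na(out))
    stop("malformed gene rule: ", sQuote(rule), call. = FALSE)
  isTRUE(out)
}
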