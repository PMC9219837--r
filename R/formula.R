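#' Parse an elemental formula
#'
#' Accepts Hill-style strings such as `"C5NO4"` or `"C6O9P"`. Element
#' tokens are an upper-case letter followed by optional lower-case letters,
#' so pseudo-elements used for conserved moieties (e.g. `"Z"` for the CoA
#' backbone, `"Nad"`/`"Ndp"` for the nicotinamide carriers, `"Ad"` for the
#' adenosine-phosphate core of ATP/ADP) parse like real elements.
#'
#' @param formula Formula string; `""` gives an empty count vector.
#' @return Named integer vector, element -> count.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("[A-Z][a-z]*[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: ", formula)
  el <- sub("[0-9]+$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  ct[is.na(ct)] <- 1L
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))[sort(unique(el))]
}

## element totals of a reaction given a formula lookup (list by met id);
## returns NULL when any participating metabolite lacks a formula
reaction_element_balance <- function(rxn, formulas) {
  tot <- numeric(0)
  for (met in names(rxn$stoichiometry)) {
    f <- formulas[[met]]
    if (is.null(f)) return(NULL)
    coef <- rxn$stoichiometry[[met]]
    for (el in names(f)) {
      cur <- tot[el]
      tot[el] <- (if (is.na(cur)) 0 else cur) + coef * f[[el]]
    }
  }
  tot
}

#' Check elemental balance of all internal reactions
#'
#' Exchange reactions (single-metabolite boundary reactions) are boundary
#' flows and are exempt. Reactions involving a metabolite without a formula
#' are skipped and listed separately.
#'
#' @param model A `metabolic_model`.
#' @param tol Absolute tolerance on element totals.
#' @return List with `imbalanced` (data frame: reaction, element, residual)
#'   and `skipped` (character vector of reaction ids lacking formulas).
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  formulas <- lapply(model$metabolites, function(m)
    if (is.null(m$formula)) NULL else parse_formula(m$formula))
  rows <- list(); skipped <- character(0)
  for (r in model$reactions) {
    if (is_exchange(r)) next
    bal <- reaction_element_balance(r, formulas)
    if (is.null(bal)) { skipped <- c(skipped, r$id); next }
    off <- bal[abs(bal) > tol]
    if (length(off))
      rows[[length(rows) + 1L]] <-
        data.frame(reaction = r$id, element = names(off),
                   residual = unname(off))
  }
  imbalanced <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(0), element = character(0),
               residual = numeric(0))
  rownames(imbalanced) <- NULL
  list(imbalanced = imbalanced, skipped = skipped)
}
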