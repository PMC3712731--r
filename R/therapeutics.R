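# Anti-cancer therapeutics: filtering of the transcribed drug corpus,
# spectrum x reversibility classification of tyrosine kinase inhibitors,
# and the mutant-set sensitivity rules.

# Receptor/enzyme families used to interpret family-level specificity
# designators ("Pan-ERBB", "Pan-FGFR", "PI3K Class I"). EGFR is the founding
# ERBB-family member (ERBB1).
.target_families <- list(
  ERBB = c("EGFR", "ERBB2", "ERBB3", "ERBB4"),
  FGFR = c("FGFR1", "FGFR2", "FGFR3", "FGFR4"),
  PI3K = c("PIK3CA", "PIK3CB", "PIK3CD", "PIK3CG")
)

strip_isoform <- function(sym) sub("([A-Z0-9])[a-z]$", "\\1", sym)

token_words <- function(tok) {
  w <- strsplit(tok, "[^A-Za-z0-9-]+")[[1]]
  w[nzchar(w)]
}

# Families a specificity token designates as a whole ("Pan-FGFR",
# "PI3K Class I", or a bare family name).
token_families <- function(tok) {
  fams <- character()
  words <- token_words(tok)
  for (f in names(.target_families)) {
    if (paste0("Pan-", f) %in% words || f %in% words) fams <- c(fams, f)
  }
  fams
}

#' Does a specificity token cover a query target?
#'
#' A query target symbol matches a specificity token when it equals the
#' token, appears as a word inside it, falls in a family the token
#' designates (e.g. `EGFR` against `Pan-ERBB`), or — when the query names a
#' family — the token is a member of that family (e.g. `FGFR` against
#' `FGFR3` or `FGFR2b`; isoform suffixes are ignored for membership).
#'
#' @param query target symbol or family name to look for.
#' @param token one entry of a therapeutic's specificity list.
#' @return Logical scalar.
#' @export
#' @examples
#' target_covers("EGFR", "Pan-ERBB")   # TRUE
#' target_covers("FGFR", "FGFR2b")     # TRUE
#' target_covers("EGFR", "ERBB2")      # FALSE
target_covers <- function(query, token) {
  q <- trimws(query); tok <- trimws(token)
  if (identical(q, tok)) return(TRUE)
  words <- token_words(tok)
  if (q %in% words) return(TRUE)
  for (f in token_families(tok)) {
    if (q == f || q %in% .target_families[[f]] ||
        strip_isoform(q) %in% .target_families[[f]]) return(TRUE)
  }
  if (q %in% names(.target_families)) {
    members <- .target_families[[q]]
    if (any(strip_isoform(words) %in% members)) return(TRUE)
  }
  FALSE
}

therapeutic_targets_symbol <- function(t, symbol) {
  any(vapply(t$specificity, function(tok) target_covers(symbol, tok),
             logical(1)))
}

#' Filter a therapeutic table
#'
#' Selects therapeutics satisfying the conjunction of the supplied
#' predicates; omitted predicates are not applied, so
#' `filter_therapeutics(rows)` returns all rows.
#'
#' @param rows list of [therapeutic()]s ([read_therapeutic_table()]).
#' @param pathway exact pathway name, or `NULL`.
#' @param kind `"small_molecule"` or `"recombinant_antibody"`, or `NULL`.
#' @param target_includes target symbol that must be covered by the
#'   specificity list (see [target_covers()]), or `NULL`.
#' @param target_excludes character vector of symbols none of which may be
#'   covered, or `NULL`.
#' @return The matching sublist.
#' @export
#' @examples
#' \dontrun{
#' drugs <- read_therapeutic_table()
#' length(filter_therapeutics(drugs, pathway = "Signaling by EGFR in Cancer",
#'                            kind = "small_molecule",
#'                            target_includes = "EGFR"))  # 9
#' }
filter_therapeutics <- function(rows, pathway = NULL, kind = NULL,
                                target_includes = NULL,
                                target_excludes = NULL) {
  keep <- vapply(rows, function(t) {
    if (!is.null(pathway) && !identical(t$pathway_name, pathway)) return(FALSE)
    if (!is.null(kind) && !identical(t$kind, kind)) return(FALSE)
    if (!is.null(target_includes) &&
        !therapeutic_targets_symbol(t, target_includes)) return(FALSE)
    if (!is.null(target_excludes) &&
        any(vapply(target_excludes, function(s)
          therapeutic_targets_symbol(t, s), logical(1)))) return(FALSE)
    TRUE
  }, logical(1))
  rows[keep]
}

#' Classify a tyrosine kinase inhibitor by spectrum and reversibility
#'
#' Small-molecule TKIs are classified along two axes: *spectrum* — specific
#' to the anchor receptor (specificity list is exactly the anchor) versus
#' broad (additional receptor tyrosine kinases, the "receptor-plus"
#' spectrum) — and *reversibility* — non-covalent binding is reversible,
#' covalent binding irreversible.
#'
#' @param t a [therapeutic()] with `kind = "small_molecule"`.
#' @param anchor_target the receptor against which the spectrum is judged;
#'   must be covered by the specificity list.
#' @return One of `"specific_reversible"`, `"specific_irreversible"`,
#'   `"broad_reversible"`, `"broad_irreversible"`.
#' @export
classify_tki <- function(t, anchor_target) {
  stopifnot(inherits(t, "therapeutic"))
  if (t$kind != "small_molecule")
    stop("'", t$name, "' is not a small molecule")
  if (!therapeutic_targets_symbol(t, anchor_target))
    stop("'", t$name, "' does not target ", anchor_target)
  specific <- length(t$specificity) == 1L &&
    identical(trimws(t$specificity[[1]]), anchor_target)
  reversible <- switch(t$binding_mode,
                       non_covalent = TRUE, covalent = FALSE,
                       stop("'", t$name, "' has no binding mode annotated"))
  paste0(if (specific) "specific" else "broad",
         if (reversible) "_reversible" else "_irreversible")
}

#' Sensitivity of a mutant set to a therapeutic
#'
#' Encodes the sensitivity rules for receptor mutant sets: mutants sensitive
#' to reversible TKIs are inhibited by non-covalent TKIs; mutants resistant
#' to non-covalent TKIs are not inhibited by them but are inhibited by
#' covalent (irreversible) TKIs — which, at the concentrations required,
#' also inhibit the wild-type receptor, so a covalent TKI is never reported
#' as `not_inhibited`; wild-type-overexpressing tumors are inhibited by the
#' recombinant antibody. Combinations the rules do not cover return
#' `"unknown"`.
#'
#' @param set_class a [mutant_set()] sensitivity class
#'   (`"reversible_sensitive"`, `"reversible_resistant"`,
#'   `"wild_type_overexpressed"`) or a `mutant_set` object.
#' @param t a [therapeutic()] assumed to target the receptor of the set.
#' @return `"inhibited"`, `"not_inhibited"` or `"unknown"`.
#' @export
#' @examples
#' erlotinib <- therapeutic("Erlotinib", "small_molecule", "ChEBI:114785",
#'                          "EGFR", binding_mode = "non_covalent")
#' sensitivity_lookup("reversible_resistant", erlotinib)  # "not_inhibited"
sensitivity_lookup <- function(set_class, t) {
  if (inherits(set_class, "mutant_set")) set_class <- set_class$sensitivity_class
  set_class <- match.arg(set_class,
    c("reversible_sensitive", "reversible_resistant",
      "wild_type_overexpressed"))
  stopifnot(inherits(t, "therapeutic"))
  if (t$kind == "recombinant_antibody") {
    return(if (set_class == "wild_type_overexpressed") "inhibited"
           else "unknown")
  }
  switch(t$binding_mode,
    covalent = "inhibited",
    non_covalent = switch(set_class,
      reversible_sensitive = "inhibited",
      reversible_resistant = "not_inhibited",
      wild_type_overexpressed = "unknown"),
    "unknown")
}
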