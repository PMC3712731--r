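# Domain record types shared by every other module. All coordinates are
# 1-based and ranges are inclusive at both ends, the convention used by
# protein sequence databases.

#' Sequence range
#'
#' An inclusive 1-based residue coordinate range on a protein sequence.
#'
#' @param start,end 1-based residue coordinates, `start <= end`.
#' @return An object of class `sequence_range`.
#' @export
#' @examples
#' sequence_range(463, 466)
sequence_range <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid sequence range: need 1 <= start <= end, got [",
         start, ", ", end, "]")
  structure(list(start = start, end = end), class = "sequence_range")
}

#' @export
format.sequence_range <- function(x, ...) paste0(x$start, "..", x$end)

#' @export
print.sequence_range <- function(x, ...) {
  cat("<sequence_range ", format(x), ">\n", sep = ""); invisible(x)
}

range_width <- function(r) r$end - r$start + 1L

# ---- modification specs ----------------------------------------------------

new_modification <- function(type, fields) {
  structure(fields, class = c(type, "modification_spec"))
}

#' Modification specifications
#'
#' Typed records describing how a mutant protein differs from its reference
#' sequence. Five kinds are modeled:
#' \describe{
#'   \item{`replaced_residue()`}{an amino-acid substitution at a stated
#'     coordinate (missense mutation).}
#'   \item{`fragment_deletion()`}{removal of an inclusive residue range
#'     (in-frame deletion). Optional `flank_first`/`flank_last` record the
#'     wild-type residues named at the range ends, checked when the
#'     modification is applied to a sequence.}
#'   \item{`fragment_insertion()`}{insertion of residues so that the first
#'     inserted residue sits at reference position `position` (i.e. between
#'     reference residues `position - 1` and `position`). The payload is
#'     either a literal `peptide` or a fragment of another reference sequence
#'     (`source_accession` + `source_range`), the form used for fusion
#'     proteins.}
#'   \item{`truncation()`}{loss of all residues after `new_end` (nonsense
#'     mutation: the stop replaces residue `new_end + 1`).}
#'   \item{`frameshift()`}{a reading-frame shift starting at `position`,
#'     replacing everything from that residue on with `tail_length` novel
#'     residues before a stop. The novel residues are unknown and are
#'     rendered as `X`.}
#' }
#'
#' @param coordinate,position 1-based residue coordinate.
#' @param from_aa,to_aa one-letter amino-acid codes; must differ.
#' @param range a [sequence_range()].
#' @param flank_first,flank_last,left_flank,right_flank optional one-letter
#'   codes of the wild-type residues stated at the modification boundaries.
#' @param peptide literal inserted peptide (one-letter string), or `NULL`.
#' @param source_accession,source_range reference-derived payload: accession
#'   of the donor sequence and the donor [sequence_range()], or `NULL`.
#' @param from_delins logical; `TRUE` when the insertion is the insert half
#'   of a deletion-insertion (delins) variant, in which case mutation-type
#'   classification reports only the deletion component.
#' @param new_end last retained reference residue.
#' @param stop_residue optional one-letter code of the reference residue
#'   replaced by the stop.
#' @param tail_length number of novel residues before the stop (>= 0).
#' @param ref_residue optional one-letter code of the reference residue at
#'   the frameshift position.
#' @return An object of class `modification_spec` (subclassed by kind).
#' @name modification_spec
NULL

#' @rdname modification_spec
#' @export
replaced_residue <- function(coordinate, from_aa, to_aa) {
  coordinate <- as.integer(coordinate)
  if (is.na(coordinate) || coordinate < 1L) stop("coordinate must be >= 1")
  if (!is_aa(from_aa) || !is_aa(to_aa))
    stop("unknown amino-acid code in replacement: ", from_aa, "/", to_aa)
  if (identical(from_aa, to_aa))
    stop("replaced residue must differ from the reference residue (",
         from_aa, coordinate, from_aa, ")")
  new_modification("replaced_residue",
                   list(coordinate = coordinate, from_aa = from_aa,
                        to_aa = to_aa))
}

#' @rdname modification_spec
#' @export
fragment_deletion <- function(range, flank_first = NA_character_,
                              flank_last = NA_character_) {
  stopifnot(inherits(range, "sequence_range"))
  new_modification("fragment_deletion",
                   list(range = range, flank_first = flank_first,
                        flank_last = flank_last))
}

#' @rdname modification_spec
#' @export
fragment_insertion <- function(position, peptide = NULL,
                               source_accession = NULL, source_range = NULL,
                               left_flank = NA_character_,
                               right_flank = NA_character_,
                               from_delins = FALSE) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("insertion position must be >= 1")
  has_pep <- !is.null(peptide)
  has_src <- !is.null(source_accession) || !is.null(source_range)
  if (has_pep == has_src)
    stop("insertion payload must be exactly one of a peptide or a ",
         "source accession + range")
  if (has_pep) {
    if (!nzchar(peptide)) stop("inserted peptide must be non-empty")
    if (!all(is_aa(strsplit(peptide, "")[[1]])))
      stop("inserted peptide contains non-amino-acid characters: ", peptide)
  } else {
    if (is.null(source_accession) || is.null(source_range))
      stop("source payload needs both an accession and a range")
    stopifnot(inherits(source_range, "sequence_range"))
  }
  new_modification("fragment_insertion",
                   list(position = position, peptide = peptide,
                        source_accession = source_accession,
                        source_range = source_range,
                        left_flank = left_flank, right_flank = right_flank,
                        from_delins = isTRUE(from_delins)))
}

#' @rdname modification_spec
#' @export
truncation <- function(new_end, stop_residue = NA_character_) {
  new_end <- as.integer(new_end)
  if (is.na(new_end) || new_end < 1L) stop("truncation new_end must be >= 1")
  new_modification("truncation",
                   list(new_end = new_end, stop_residue = stop_residue))
}

#' @rdname modification_spec
#' @export
frameshift <- function(position, tail_length, ref_residue = NA_character_) {
  position <- as.integer(position); tail_length <- as.integer(tail_length)
  if (is.na(position) || position < 1L) stop("frameshift position must be >= 1")
  if (is.na(tail_length) || tail_length < 0L)
    stop("frameshift tail_length must be >= 0")
  new_modification("frameshift",
                   list(position = position, tail_length = tail_length,
                        ref_residue = ref_residue))
}

mod_type <- function(spec) class(spec)[[1]]

#' @export
print.modification_spec <- function(x, ...) {
  cat("<", mod_type(x), "> ", sep = "")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# ---- JSON (de)serialization of modification specs --------------------------

#' Serialize modification specs to and from plain lists / JSON
#'
#' `mod_to_list()` converts a [modification_spec] to a plain named list with
#' a `type` discriminator; `mod_from_list()` inverts it. The pair is a
#' lossless round trip and underlies the package's JSON model documents.
#'
#' @param spec a [modification_spec].
#' @param x a plain list as produced by `mod_to_list()` (or parsed from
#'   JSON with `simplifyVector = FALSE`).
#' @return `mod_to_list()` a list; `mod_from_list()` a [modification_spec].
#' @export
mod_to_list <- function(spec) {
  stopifnot(inherits(spec, "modification_spec"))
  out <- list(type = mod_type(spec))
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (inherits(v, "sequence_range")) v <- list(start = v$start, end = v$end)
    out[[nm]] <- v
  }
  out
}

#' @rdname mod_to_list
#' @export
mod_from_list <- function(x) {
  type <- x$type
  if (is.null(type)) stop("modification record lacks a 'type' field")
  as_chr <- function(v) if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
  switch(type,
    replaced_residue = replaced_residue(x$coordinate, x$from_aa, x$to_aa),
    fragment_deletion = fragment_deletion(
      sequence_range(x$range$start, x$range$end),
      flank_first = as_chr(x$flank_first), flank_last = as_chr(x$flank_last)),
    fragment_insertion = fragment_insertion(
      x$position, peptide = x$peptide,
      source_accession = x$source_accession,
      source_range = if (!is.null(x$source_range))
        sequence_range(x$source_range$start, x$source_range$end),
      left_flank = as_chr(x$left_flank), right_flank = as_chr(x$right_flank),
      from_delins = isTRUE(x$from_delins)),
    truncation = truncation(x$new_end, stop_residue = as_chr(x$stop_residue)),
    frameshift = frameshift(x$position, x$tail_length,
                            ref_residue = as_chr(x$ref_residue)),
    stop("unknown modification type: ", type)
  )
}

# ---- disease term ----------------------------------------------------------

#' Disease Ontology term
#'
#' A disease annotation: a numeric Disease Ontology (DO) identifier, a label,
#' and an optional National Cancer Institute Thesaurus (NCIt)
#' cross-reference. Identifiers are opaque; no ontology reasoning is done.
#'
#' @param do_id positive integer DO identifier.
#' @param name non-empty label.
#' @param ncit_xref optional opaque NCIt identifier.
#' @return An object of class `disease_term`.
#' @export
#' @examples
#' disease_term(3075, "adult glioblastoma multiforme")
disease_term <- function(do_id, name, ncit_xref = NA_character_) {
  do_id <- as.integer(do_id)
  if (is.na(do_id) || do_id <= 0L) stop("do_id must be a positive integer")
  if (!is.character(name) || !nzchar(name)) stop("disease name must be non-empty")
  structure(list(do_id = do_id, name = name, ncit_xref = ncit_xref),
            class = "disease_term")
}

#' @export
format.disease_term <- function(x, ...) paste0("DOID:", x$do_id, " ", x$name)

#' @export
print.disease_term <- function(x, ...) {
  cat("<disease_term ", format(x), ">\n", sep = ""); invisible(x)
}

# Key used for set semantics over disease terms.
term_key <- function(term) as.character(term$do_id)

# Add terms to a list of disease_terms with set (deduplicating) semantics.
union_terms <- function(terms, new_terms) {
  all <- c(terms, new_terms)
  all[!duplicated(vapply(all, term_key, character(1)))]
}

# ---- variant entity --------------------------------------------------------

#' Variant entity (entity with accessioned sequence)
#'
#' A protein-level disease variant: a reference accession with the retained
#' coordinate range, an ordered list of [modification_spec]s, plus display
#' name, disease terms and database cross-references. This mirrors how
#' pathway databases model a mutant protein as a reference sequence with
#' start/end coordinates and a modification list.
#'
#' @param gene gene symbol.
#' @param reference_accession opaque reference-sequence identifier.
#' @param ref_range [sequence_range()] of retained reference residues.
#' @param modifications list of [modification_spec]s (may be empty).
#' @param display_name human-readable variant name; round-trips through the
#'   nomenclature formatter.
#' @param isoform optional isoform suffix (e.g. the `b`/`c` splice forms of
#'   FGFR receptors), `NA` if none.
#' @param diseases list of [disease_term()]s (set semantics).
#' @param cosmic_ids character vector of opaque COSMIC identifiers.
#' @param pathway_name name of the pathway the variant is annotated under.
#' @return An object of class `variant_entity`.
#' @export
variant_entity <- function(gene, reference_accession, ref_range,
                           modifications = list(), display_name = gene,
                           isoform = NA_character_, diseases = list(),
                           cosmic_ids = character(), pathway_name = "") {
  stopifnot(inherits(ref_range, "sequence_range"))
  entity <- structure(
    list(gene = gene, isoform = isoform,
         reference_accession = reference_accession, ref_range = ref_range,
         modifications = modifications, display_name = display_name,
         diseases = diseases, cosmic_ids = unique(as.character(cosmic_ids)),
         pathway_name = pathway_name),
    class = "variant_entity")
  entity
}

#' @export
print.variant_entity <- function(x, ...) {
  cat("<variant_entity> ", x$display_name, " [", x$reference_accession, " ",
      format(x$ref_range), "] ", length(x$modifications), " modification(s)\n",
      sep = "")
  invisible(x)
}

#' Validate a variant entity
#'
#' Checks every structural invariant of a [variant_entity()] and reports
#' violations as data (a character vector), not errors: modification
#' coordinates must fall inside the retained reference range (insertions may
#' additionally be anchored at `ref_range$end + 1`, the fusion append
#' position), replacements must change the residue, and deletion ranges must
#' not overlap each other. The check is idempotent and independent of
#' modification order.
#'
#' @param entity a [variant_entity()].
#' @return Character vector of violation messages; empty when the entity is
#'   valid.
#' @export
#' @examples
#' ref <- sequence_range(1, 724)
#' e <- variant_entity("PIK3R1", "SYN_PIK3R1", ref,
#'                     list(fragment_deletion(sequence_range(463, 466))))
#' validate_entity(e)  # character(0)
validate_entity <- function(entity) {
  v <- character()
  say <- function(...) v[[length(v) + 1L]] <<- paste0(...)
  if (!inherits(entity, "variant_entity")) return("not a variant_entity")
  rr <- entity$ref_range
  in_range <- function(p) p >= rr$start && p <= rr$end
  del_ranges <- list()
  for (m in entity$modifications) {
    switch(mod_type(m),
      replaced_residue = {
        if (!in_range(m$coordinate))
          say("replacement coordinate ", m$coordinate,
              " outside reference range ", format(rr))
      },
      fragment_deletion = {
        if (!in_range(m$range$start) || !in_range(m$range$end))
          say("deletion range ", format(m$range),
              " outside reference range ", format(rr))
        del_ranges[[length(del_ranges) + 1L]] <- m$range
      },
      fragment_insertion = {
        ok <- in_range(m$position) || m$position == rr$end + 1L
        if (!ok)
          say("insertion position ", m$position,
              " outside reference range ", format(rr), " (+1)")
      },
      truncation = {
        if (m$new_end < rr$start - 1L || m$new_end > rr$end)
          say("truncation end ", m$new_end,
              " outside reference range ", format(rr))
      },
      frameshift = {
        if (!in_range(m$position))
          say("frameshift position ", m$position,
              " outside reference range ", format(rr))
      },
      say("unknown modification type: ", mod_type(m))
    )
  }
  if (length(del_ranges) > 1L) {
    ord <- order(vapply(del_ranges, `[[`, integer(1), "start"))
    del_ranges <- del_ranges[ord]
    for (i in seq_len(length(del_ranges) - 1L)) {
      if (del_ranges[[i]]$end >= del_ranges[[i + 1L]]$start)
        say("overlapping deletion ranges ", format(del_ranges[[i]]),
            " and ", format(del_ranges[[i + 1L]]))
    }
  }
  sort(v)
}

# ---- therapeutic -----------------------------------------------------------

#' Anti-cancer therapeutic
#'
#' A small-molecule inhibitor or recombinant antibody, with its target
#' specificity (ordered list of target symbols or family designators such as
#' `Pan-ERBB`), binding mode and pathway. Binding modes: `covalent`
#' (irreversible), `non_covalent` (reversible), `not_applicable`
#' (antibodies, which must use this value).
#'
#' @param name drug name.
#' @param kind `"small_molecule"` or `"recombinant_antibody"`.
#' @param reference_id opaque ChEBI-style identifier, `"Pending"`, or the
#'   literal `"Recombinant antibody"` marker.
#' @param specificity non-empty character vector of target symbols.
#' @param binding_mode `"covalent"`, `"non_covalent"` or `"not_applicable"`.
#' @param pathway_name pathway the therapeutic is annotated under.
#' @return An object of class `therapeutic`.
#' @export
therapeutic <- function(name, kind, reference_id, specificity,
                        binding_mode = "non_covalent", pathway_name = "") {
  kind <- match.arg(kind, c("small_molecule", "recombinant_antibody"))
  binding_mode <- match.arg(binding_mode,
                            c("covalent", "non_covalent", "not_applicable"))
  if (length(specificity) == 0L || !any(nzchar(specificity)))
    stop("therapeutic '", name, "' must have a non-empty specificity list")
  if (kind == "recombinant_antibody" && binding_mode != "not_applicable")
    stop("recombinant antibodies must use binding_mode 'not_applicable'")
  structure(list(name = name, kind = kind, reference_id = reference_id,
                 specificity = as.character(specificity),
                 binding_mode = binding_mode, pathway_name = pathway_name),
            class = "therapeutic")
}

#' @export
print.therapeutic <- function(x, ...) {
  cat("<therapeutic> ", x$name, " (", x$kind, ", ", x$binding_mode, ") -> ",
      paste(x$specificity, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mutant sensitivity set
#'
#' A named set of variant display names sharing a sensitivity class towards
#' tyrosine kinase inhibitors: `reversible_sensitive` (inhibited by low
#' concentrations of non-covalent TKIs), `reversible_resistant` (resistant to
#' non-covalent TKIs but inhibited by covalent ones), or
#' `wild_type_overexpressed` (wild-type receptor overexpression, the target
#' of recombinant antibodies).
#'
#' @param name set name.
#' @param members non-empty character vector of variant display names.
#' @param sensitivity_class one of the three classes above.
#' @return An object of class `mutant_set`.
#' @export
mutant_set <- function(name, members, sensitivity_class) {
  sensitivity_class <- match.arg(
    sensitivity_class,
    c("reversible_sensitive", "reversible_resistant", "wild_type_overexpressed"))
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("mutant set must have at least one member")
  structure(list(name = name, members = members,
                 sensitivity_class = sensitivity_class),
            class = "mutant_set")
}
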