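# Parser and formatter for the protein-variant naming dialect used in the
# packaged variant corpus: "GENE L858R", "GENE Y463_L466del",
# "GENE D770_N771insNPG", "GENE E746_S752delinsV", "GENE R130*",
# "GENE 795fs*139STOP", compound descriptors split on ";", fusion
# "GENE1-GENE2", and named aliases (EGFRvIII) resolved through a registry.

.gene_re <- "^([A-Z][A-Z0-9]*)([a-z]?)$"
.fusion_re <- "^([A-Z][A-Z0-9]*)-([A-Z][A-Z0-9]*)$"

#' Parsed variant
#'
#' Result of [parse_variant_token()]: gene symbol, optional isoform suffix,
#' the ordered [modification_spec] list, and fusion information. For fusion
#' tokens (`GENE1-GENE2`) the spec list is empty until breakpoints are
#' supplied to [build_fusion()].
#'
#' @param gene gene symbol.
#' @param specs list of [modification_spec]s.
#' @param isoform optional isoform suffix (single lowercase letter), `NA` if
#'   none.
#' @param is_fusion logical.
#' @param fusion_partner partner gene symbol (fusions only).
#' @param alias original alias name when the token was resolved through the
#'   alias registry, `NA` otherwise.
#' @return An object of class `parsed_variant`.
#' @export
parsed_variant <- function(gene, specs = list(), isoform = NA_character_,
                           is_fusion = FALSE, fusion_partner = NA_character_,
                           alias = NA_character_) {
  if (isTRUE(is_fusion) != !is.na(fusion_partner))
    stop("is_fusion and fusion_partner must be set together")
  structure(list(gene = gene, isoform = isoform, specs = specs,
                 is_fusion = isTRUE(is_fusion),
                 fusion_partner = fusion_partner, alias = alias),
            class = "parsed_variant")
}

#' @export
print.parsed_variant <- function(x, ...) {
  cat("<parsed_variant> ", format_variant(x), " (",
      if (x$is_fusion) "fusion" else paste(length(x$specs), "spec(s)"),
      ")\n", sep = "")
  invisible(x)
}

#' Load the variant alias registry
#'
#' Named variant aliases (such as `EGFRvIII`) whose residue coordinates are
#' not derivable from the name itself; coordinates in the bundled registry
#' are curator-supplied.
#'
#' @param path registry TSV; defaults to the bundled file.
#' @return Data frame with columns `alias`, `gene`, `spec`, `note`.
#' @export
load_alias_registry <- function(path = system.file("extdata",
                                                   "alias_registry.tsv",
                                                   package = "pathvar")) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = "character")
}

parse_registry_spec <- function(spec_str, alias) {
  specs <- list()
  for (part in strsplit(spec_str, ";", fixed = TRUE)[[1]]) {
    m <- regmatches(part, regexec("^del:([0-9]+)-([0-9]+)$", part))[[1]]
    if (length(m) == 3L) {
      specs[[length(specs) + 1L]] <-
        fragment_deletion(sequence_range(as.integer(m[2]), as.integer(m[3])))
    } else {
      stop("alias registry entry for '", alias,
           "' has unsupported spec fragment '", part, "'")
    }
  }
  specs
}

parse_descriptor <- function(d, token) {
  syntax_error <- function() {
    stop("cannot parse variant descriptor '", d, "' in token '", token, "'")
  }
  grab <- function(re) {
    m <- regmatches(d, regexec(re, d))[[1]]
    if (length(m)) m[-1] else NULL
  }
  # delins before ins/del: the longer suffix must win
  if (!is.null(m <- grab("^([A-Z])([0-9]+)_([A-Z])([0-9]+)delins([A-Z]+)$"))) {
    p1 <- as.integer(m[2]); p2 <- as.integer(m[4])
    if (p2 < p1) syntax_error()
    return(list(
      fragment_deletion(sequence_range(p1, p2),
                        flank_first = m[1], flank_last = m[3]),
      fragment_insertion(p1, peptide = m[5], from_delins = TRUE)))
  }
  if (!is.null(m <- grab("^([A-Z])([0-9]+)_([A-Z])([0-9]+)ins([A-Z]+)$"))) {
    p1 <- as.integer(m[2]); p2 <- as.integer(m[4])
    if (p2 != p1 + 1L)
      stop("insertion flanks must be adjacent residues in '", d,
           "' (got positions ", p1, " and ", p2, ")")
    return(list(fragment_insertion(p2, peptide = m[5],
                                   left_flank = m[1], right_flank = m[3])))
  }
  if (!is.null(m <- grab("^([A-Z])([0-9]+)_([A-Z])([0-9]+)del$"))) {
    p1 <- as.integer(m[2]); p2 <- as.integer(m[4])
    if (p2 < p1) syntax_error()
    return(list(fragment_deletion(sequence_range(p1, p2),
                                  flank_first = m[1], flank_last = m[3])))
  }
  if (!is.null(m <- grab("^([A-Z])([0-9]+)del$"))) {
    p <- as.integer(m[2])
    return(list(fragment_deletion(sequence_range(p, p),
                                  flank_first = m[1], flank_last = m[1])))
  }
  if (!is.null(m <- grab("^([A-Z])([0-9]+)\\*$"))) {
    p <- as.integer(m[2])
    if (p < 2L) stop("nonsense mutation at position ", p,
                     " leaves no retained residues in '", d, "'")
    return(list(truncation(p - 1L, stop_residue = m[1])))
  }
  if (!is.null(m <- grab("^([A-Z]?)([0-9]+)fs\\*([0-9]+)STOP$"))) {
    aa <- if (nzchar(m[1])) m[1] else NA_character_
    return(list(frameshift(as.integer(m[2]), as.integer(m[3]),
                           ref_residue = aa)))
  }
  if (!is.null(m <- grab("^([A-Z])([0-9]+)([A-Z])$"))) {
    if (!is_aa(m[1]) || !is_aa(m[3])) syntax_error()
    return(list(replaced_residue(as.integer(m[2]), m[1], m[3])))
  }
  syntax_error()
}

#' Parse a variant token
#'
#' Parses a variant name of the form `"<GENE> <descriptor>[;<descriptor>...]"`
#' into a [parsed_variant()]. The descriptor grammar covers missense
#' (`L858R`), range deletion (`Y463_L466del`), single-residue deletion
#' (`K459del`), deletion-insertion (`E746_S752delinsV`, represented as a
#' deletion plus an insertion anchored at the deletion start), insertion
#' between adjacent residues (`D770_N771insNPG`), nonsense (`R130*`, modeled
#' as truncation at the preceding residue), and frameshift (`795fs*139STOP`,
#' optionally amino-acid-prefixed). Two-symbol tokens joined by `-`
#' (`BCR-FGFR1`) are fusions; single tokens with internal lowercase
#' (`EGFRvIII`) are resolved through the alias registry; a trailing single
#' lowercase letter on the gene symbol (`FGFR2b`) is captured as an isoform
#' suffix. Surrounding whitespace is ignored and compound descriptors may be
#' separated by `";"` with or without a following space.
#'
#' @param token variant token, e.g. `"EGFR L858R"`.
#' @param aliases alias registry data frame ([load_alias_registry()]).
#' @return A [parsed_variant()].
#' @export
#' @examples
#' parse_variant_token("EGFR L858R")
#' parse_variant_token("PIK3R1 Y463_L466del")
#' parse_variant_token("BCR-FGFR1")
parse_variant_token <- function(token, aliases = load_alias_registry()) {
  if (!is.character(token) || length(token) != 1L)
    stop("token must be a single character string")
  tok <- trimws(token)
  if (!nzchar(tok)) stop("cannot parse empty variant token")
  tok <- gsub("[[:space:]]+", " ", tok)
  words <- strsplit(tok, " ", fixed = TRUE)[[1]]

  if (length(words) == 1L) {
    w <- words[[1]]
    hit <- which(aliases$alias == w)
    if (length(hit) == 1L) {
      row <- aliases[hit, ]
      return(parsed_variant(gene = row$gene, alias = w,
                            specs = parse_registry_spec(row$spec, w)))
    }
    m <- regmatches(w, regexec(.fusion_re, w))[[1]]
    if (length(m) == 3L)
      return(parsed_variant(gene = m[2], is_fusion = TRUE,
                            fusion_partner = m[3]))
    m <- regmatches(w, regexec(.gene_re, w))[[1]]
    if (length(m) == 3L)
      return(parsed_variant(gene = m[2],
                            isoform = if (nzchar(m[3])) m[3] else NA_character_))
    if (grepl("[a-z]", w))
      stop("unknown variant alias '", w, "'")
    stop("cannot parse variant token '", token, "'")
  }

  gene_tok <- words[[1]]
  m <- regmatches(gene_tok, regexec(.gene_re, gene_tok))[[1]]
  if (length(m) != 3L)
    stop("cannot parse gene symbol '", gene_tok, "' in token '", token, "'")
  gene <- m[2]
  isoform <- if (nzchar(m[3])) m[3] else NA_character_

  descriptor <- paste(words[-1], collapse = " ")
  parts <- trimws(strsplit(descriptor, ";", fixed = TRUE)[[1]])
  if (!all(nzchar(parts)))
    stop("empty descriptor component in token '", token, "'")
  specs <- list()
  for (p in parts) specs <- c(specs, parse_descriptor(p, token))
  parsed_variant(gene = gene, isoform = isoform, specs = specs)
}

format_descriptor_specs <- function(specs) {
  out <- character()
  i <- 1L
  n <- length(specs)
  fl <- function(x, default = "X") if (is.na(x)) default else x
  while (i <= n) {
    s <- specs[[i]]
    nxt <- if (i < n) specs[[i + 1L]] else NULL
    if (mod_type(s) == "fragment_deletion" && !is.null(nxt) &&
        mod_type(nxt) == "fragment_insertion" && isTRUE(nxt$from_delins) &&
        nxt$position == s$range$start) {
      out <- c(out, paste0(fl(s$flank_first), s$range$start, "_",
                           fl(s$flank_last), s$range$end, "delins",
                           nxt$peptide))
      i <- i + 2L
      next
    }
    out <- c(out, switch(mod_type(s),
      replaced_residue = paste0(s$from_aa, s$coordinate, s$to_aa),
      fragment_deletion = if (range_width(s$range) == 1L)
        paste0(fl(s$flank_first), s$range$start, "del")
      else paste0(fl(s$flank_first), s$range$start, "_",
                  fl(s$flank_last), s$range$end, "del"),
      fragment_insertion = paste0(fl(s$left_flank), s$position - 1L, "_",
                                  fl(s$right_flank), s$position, "ins",
                                  s$peptide %||% paste0("<", s$source_accession,
                                                        ":", format(s$source_range), ">")),
      truncation = paste0(fl(s$stop_residue), s$new_end + 1L, "*"),
      frameshift = paste0(if (is.na(s$ref_residue)) "" else s$ref_residue,
                          s$position, "fs*", s$tail_length, "STOP"),
      stop("cannot format modification of type ", mod_type(s))))
    i <- i + 1L
  }
  out
}

#' Format a parsed variant as its canonical token
#'
#' Inverse of [parse_variant_token()]: `parse_variant_token(format_variant(p))`
#' reproduces `p`. Compound descriptors are joined with `";"` and no space,
#' the canonical spelling (tokens written with `"; "` parse identically but
#' re-format without the space). Fusions format as `GENE1-GENE2` and aliases
#' as the alias name.
#'
#' @param parsed a [parsed_variant()].
#' @return Canonical token string.
#' @export
#' @examples
#' format_variant(parse_variant_token("EGFR  L858R "))  # "EGFR L858R"
format_variant <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_variant"))
  if (!is.na(parsed$alias)) return(parsed$alias)
  if (parsed$is_fusion)
    return(paste0(parsed$gene, "-", parsed$fusion_partner))
  gene <- paste0(parsed$gene,
                 if (is.na(parsed$isoform)) "" else parsed$isoform)
  if (length(parsed$specs) == 0L) return(gene)
  paste(gene, paste(format_descriptor_specs(parsed$specs), collapse = ";"))
}

#' Classify the mutation type of a parsed variant
#'
#' Maps the modification specs to the standard mutation-type vocabulary:
#' `Missense`, `Deletion`, `Insertion`, `Nonsense`, `Frameshift`, or
#' `Translocation` for fusions. Compound variants yield a `"; "`-joined
#' label in spec order. Deletion-insertions (delins) report only their
#' deletion component, matching how such variants are catalogued.
#'
#' @param parsed a [parsed_variant()].
#' @return Character scalar mutation-type label.
#' @export
#' @examples
#' classify_mutation_type(parse_variant_token("EGFR E746_A750del; T790M"))
classify_mutation_type <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_variant"))
  if (parsed$is_fusion) return("Translocation")
  if (length(parsed$specs) == 0L)
    stop("cannot classify a variant with no modifications")
  labels <- character()
  for (s in parsed$specs) {
    if (mod_type(s) == "fragment_insertion" && isTRUE(s$from_delins)) next
    labels <- c(labels, switch(mod_type(s),
      replaced_residue = "Missense",
      fragment_deletion = "Deletion",
      fragment_insertion = "Insertion",
      truncation = "Nonsense",
      frameshift = "Frameshift"))
  }
  paste(labels, collapse = "; ")
}
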