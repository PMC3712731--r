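# Construction of mutant and fusion protein sequences. Every modification is
# anchored in *reference* coordinates; application first restricts to the
# retained reference range, then edits by reference position, so the
# bookkeeping never depends on earlier edits shifting coordinates.

#' Reference protein sequence
#'
#' @param accession opaque sequence identifier.
#' @param gene gene symbol.
#' @param residues uppercase one-letter residue string (standard alphabet
#'   plus `X`).
#' @param isoform optional isoform suffix.
#' @return An object of class `reference_sequence`.
#' @export
reference_sequence <- function(accession, gene, residues,
                               isoform = NA_character_) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  chars <- strsplit(residues, "")[[1]]
  bad <- unique(chars[!is_aa(chars)])
  if (length(bad))
    stop("reference sequence '", accession,
         "' contains non-amino-acid characters: ", paste(bad, collapse = ""))
  structure(list(accession = accession, gene = gene, isoform = isoform,
                 residues = residues),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat("<reference_sequence> ", x$accession, " (", x$gene,
      if (!is.na(x$isoform)) x$isoform else "", "), ",
      nchar(x$residues), " aa\n", sep = "")
  invisible(x)
}

seq_len_aa <- function(ref) nchar(ref$residues)

residue_at <- function(ref, pos) substr(ref$residues, pos, pos)

check_wt_residue <- function(ref, pos, expected, what) {
  if (is.na(expected)) return(invisible(TRUE))
  found <- residue_at(ref, pos)
  if (!identical(found, expected))
    stop("residue mismatch for ", what, " at coordinate ", pos,
         ": expected ", expected, ", found ", found,
         " in ", ref$accession)
  invisible(TRUE)
}

#' Apply modifications to a reference sequence
#'
#' Builds the mutant residue string for a [variant_entity()]: the sequence is
#' first restricted to `entity$ref_range`, then deletions, insertions,
#' replacements, truncations and frameshifts are applied, all anchored at
#' reference coordinates. Wild-type residues stated in the specs (replacement
#' `from_aa`, deletion/insertion flanks, nonsense stop residue, frameshift
#' residue) are checked against the reference and a mismatch raises an error
#' naming the coordinate, the expected and the found residue. Overlapping
#' deletions, or a replacement falling inside a deleted range, are rejected
#' as conflicts.
#'
#' Length algebra: replacements preserve length, a deletion removes
#' `end - start + 1` residues, an insertion adds its payload length, and a
#' frameshift yields the prefix up to `position - 1` plus `tail_length`
#' `X` residues.
#'
#' @param ref a [reference_sequence()].
#' @param entity a [variant_entity()] whose `ref_range` lies within `ref`.
#' @param sources named list of donor [reference_sequence()]s for
#'   reference-derived insertion payloads (fusions), keyed by accession.
#' @return Mutant residue string.
#' @export
#' @examples
#' ref <- reference_sequence("SYN_EGFR", "EGFR",
#'                           paste(rep("A", 900), collapse = ""))
#' ref$residues <- `substr<-`(ref$residues, 858, 858, "L")
#' ent <- variant_entity("EGFR", "SYN_EGFR", sequence_range(1, 900),
#'                       list(replaced_residue(858, "L", "R")))
#' substr(apply_modifications(ref, ent), 858, 858)  # "R"
apply_modifications <- function(ref, entity, sources = list()) {
  stopifnot(inherits(ref, "reference_sequence"),
            inherits(entity, "variant_entity"))
  rr <- entity$ref_range
  if (rr$end > seq_len_aa(ref))
    stop("reference range ", format(rr), " exceeds length of ",
         ref$accession, " (", seq_len_aa(ref), " aa)")
  problems <- validate_entity(entity)
  if (length(problems))
    stop("invalid variant entity '", entity$display_name, "': ",
         paste(problems, collapse = "; "))

  positions <- rr$start:rr$end
  keep <- rep(TRUE, length(positions))          # indexed by positions
  pieces <- strsplit(substr(ref$residues, rr$start, rr$end), "")[[1]]
  prefix <- rep("", length(positions))          # insertions before position i
  suffix_tail <- ""                             # appended after range end
  idx <- function(p) p - rr$start + 1L

  deleted <- rep(FALSE, length(positions))
  fs <- NULL
  for (m in entity$modifications) {
    switch(mod_type(m),
      fragment_deletion = {
        check_wt_residue(ref, m$range$start, m$flank_first, "deletion start")
        check_wt_residue(ref, m$range$end, m$flank_last, "deletion end")
        span <- idx(m$range$start):idx(m$range$end)
        if (any(deleted[span]))
          stop("conflicting deletions overlap at ", format(m$range),
               " in '", entity$display_name, "'")
        deleted[span] <- TRUE
        keep[span] <- FALSE
      },
      truncation = {
        if (!is.na(m$stop_residue) && m$new_end + 1L <= rr$end)
          check_wt_residue(ref, m$new_end + 1L, m$stop_residue,
                           "nonsense position")
        if (m$new_end < rr$end) keep[idx(m$new_end + 1L):idx(rr$end)] <- FALSE
      },
      NULL)
  }
  for (m in entity$modifications) {
    switch(mod_type(m),
      fragment_insertion = {
        if (!is.na(m$left_flank))
          check_wt_residue(ref, m$position - 1L, m$left_flank,
                           "insertion left flank")
        if (!is.na(m$right_flank))
          check_wt_residue(ref, m$position, m$right_flank,
                           "insertion right flank")
        payload <- if (!is.null(m$peptide)) m$peptide else {
          src <- sources[[m$source_accession]]
          if (is.null(src))
            stop("no source sequence supplied for insertion payload '",
                 m$source_accession, "'")
          if (m$source_range$end > seq_len_aa(src))
            stop("source range ", format(m$source_range),
                 " exceeds length of ", src$accession)
          substr(src$residues, m$source_range$start, m$source_range$end)
        }
        if (m$position == rr$end + 1L) {
          suffix_tail <- paste0(suffix_tail, payload)
        } else {
          prefix[idx(m$position)] <- paste0(prefix[idx(m$position)], payload)
        }
      },
      replaced_residue = {
        check_wt_residue(ref, m$coordinate, m$from_aa, "replacement")
        if (deleted[idx(m$coordinate)])
          stop("replacement at ", m$coordinate,
               " conflicts with a deletion covering that coordinate in '",
               entity$display_name, "'")
        pieces[idx(m$coordinate)] <- m$to_aa
      },
      frameshift = {
        check_wt_residue(ref, m$position, m$ref_residue, "frameshift")
        if (!is.null(fs)) stop("multiple frameshifts in one entity")
        fs <- m
      },
      NULL)
  }
  if (!is.null(fs)) {
    if (fs$position <= rr$end) keep[idx(fs$position):idx(rr$end)] <- FALSE
    suffix_tail <- paste0(strrep("X", fs$tail_length), suffix_tail)
  }
  body <- paste0(prefix[keep], pieces[keep], collapse = "")
  paste0(body, suffix_tail)
}

#' Build a fusion protein from a truncated host and an inserted fragment
#'
#' Models a translocation product: the host protein truncated to
#' `host_range`, followed by the residues `insert_range` of the partner
#' protein, recorded as a [variant_entity()] whose single
#' [fragment_insertion()] is anchored at `host_range$end + 1` and points at
#' the partner accession. The mutation type of such an entity is
#' `Translocation`.
#'
#' @param host,insert [reference_sequence()]s for host and partner.
#' @param host_range,insert_range [sequence_range()]s of the retained host
#'   segment and the fused partner fragment.
#' @return A list with `entity` (the [variant_entity()]) and `residues`
#'   (the fusion residue string, `host[host_range]` followed by
#'   `insert[insert_range]`).
#' @export
#' @examples
#' host <- reference_sequence("SYN_BCR", "BCR", strrep("A", 600))
#' part <- reference_sequence("SYN_FGFR1", "FGFR1", strrep("G", 850))
#' fus <- build_fusion(host, sequence_range(1, 584),
#'                     part, sequence_range(429, 822))
#' fus$entity$modifications[[1]]$position  # 585
#' nchar(fus$residues)                     # 978
build_fusion <- function(host, host_range, insert, insert_range) {
  stopifnot(inherits(host, "reference_sequence"),
            inherits(insert, "reference_sequence"),
            inherits(host_range, "sequence_range"),
            inherits(insert_range, "sequence_range"))
  if (host_range$end > seq_len_aa(host))
    stop("host range ", format(host_range), " exceeds length of ",
         host$accession, " (", seq_len_aa(host), " aa)")
  if (insert_range$end > seq_len_aa(insert))
    stop("insert range ", format(insert_range), " exceeds length of ",
         insert$accession, " (", seq_len_aa(insert), " aa)")
  ins <- fragment_insertion(host_range$end + 1L,
                            source_accession = insert$accession,
                            source_range = insert_range)
  entity <- variant_entity(
    gene = host$gene, reference_accession = host$accession,
    ref_range = host_range, modifications = list(ins),
    display_name = paste0(host$gene, "-", insert$gene))
  residues <- apply_modifications(
    host, entity, sources = stats::setNames(list(insert), insert$accession))
  list(entity = entity, residues = residues)
}

# ---- FASTA -----------------------------------------------------------------

#' Read and write reference sequences as FASTA
#'
#' Thin wrappers over Biostrings. FASTA headers are written as
#' `accession gene=SYMBOL[ isoform=x]` and parsed back into
#' [reference_sequence()] fields; sequences wrap at 60 columns.
#'
#' @param path FASTA file path.
#' @param refs list of [reference_sequence()]s.
#' @return `read_fasta_refs()` a named list of [reference_sequence()]s keyed
#'   by accession; `write_fasta_refs()` returns `path` invisibly.
#' @export
read_fasta_refs <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  refs <- lapply(seq_along(set), function(i) {
    header <- names(set)[[i]]
    fields <- strsplit(header, " ", fixed = TRUE)[[1]]
    accession <- fields[[1]]
    kv <- fields[-1][grepl("=", fields[-1], fixed = TRUE)]
    kvs <- strsplit(kv, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kvs, `[[`, character(1), 2L),
                            vapply(kvs, `[[`, character(1), 1L))
    reference_sequence(
      accession = accession,
      gene = if ("gene" %in% names(vals)) vals[["gene"]] else accession,
      isoform = if ("isoform" %in% names(vals)) vals[["isoform"]]
                else NA_character_,
      residues = as.character(set[[i]]))
  })
  stats::setNames(refs, vapply(refs, `[[`, character(1), "accession"))
}

#' @rdname read_fasta_refs
#' @export
write_fasta_refs <- function(refs, path) {
  headers <- vapply(refs, function(r) {
    h <- paste0(r$accession, " gene=", r$gene)
    if (!is.na(r$isoform)) h <- paste0(h, " isoform=", r$isoform)
    h
  }, character(1))
  set <- Biostrings::AAStringSet(vapply(refs, `[[`, character(1), "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
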