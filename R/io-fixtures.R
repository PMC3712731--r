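# Readers for the transcribed variant and therapeutic corpora, the
# synthetic reference-sequence generator, and JSON model export/import.
# TSV dialect: tab-separated, no quoting, UTF-8, Unix newlines.

default_variant_table <- function()
  system.file("extdata", "table1_variants.tsv", package = "pathvar")

default_therapeutic_table <- function()
  system.file("extdata", "table2_therapeutics.tsv", package = "pathvar")

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character",
                          fill = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("malformed table '", basename(path), "': missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read the variant corpus
#'
#' Reads a variant table (five tab-separated columns: `disease_variant`,
#' `cosmic_ids`, `mutation_type`, `disease`, `pathway`) into one record per
#' row. The `disease_variant` cell is the published display name; its
#' trailing `" mutant"` / `" fusion mutant"` qualifier is stripped to obtain
#' the parseable variant token, from which the gene symbol (isoform suffix
#' removed) is taken. COSMIC cells may hold several comma-separated ids;
#' empty cells give an empty set. Disease cells are `";"`-separated
#' free-text atoms.
#'
#' @param path TSV path; defaults to the bundled transcription of the
#'   published cancer-variant corpus (151 records).
#' @param aliases alias registry for token parsing.
#' @return Data frame with columns `display_name`, `token`, `gene`,
#'   `isoform`, `cosmic_ids` (list column of character vectors),
#'   `mutation_type`, `disease`, `pathway`.
#' @export
#' @examples
#' \dontrun{
#' v <- read_variant_table()
#' nrow(v)  # 151
#' }
read_variant_table <- function(path = default_variant_table(),
                               aliases = load_alias_registry()) {
  df <- read_tsv_checked(path, c("disease_variant", "cosmic_ids",
                                 "mutation_type", "disease", "pathway"))
  if (nrow(df) == 0L) {
    return(data.frame(display_name = character(), token = character(),
                      gene = character(), isoform = character(),
                      cosmic_ids = I(list()), mutation_type = character(),
                      disease = character(), pathway = character(),
                      stringsAsFactors = FALSE))
  }
  token <- sub(" fusion mutant$", "", df$disease_variant)
  token <- sub(" mutant$", "", token)
  parsed <- lapply(token, parse_variant_token, aliases = aliases)
  cosmic <- lapply(df$cosmic_ids, function(cell) {
    cell <- trimws(cell)
    if (!nzchar(cell)) character()
    else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  })
  out <- data.frame(
    display_name = df$disease_variant,
    token = token,
    gene = vapply(parsed, `[[`, character(1), "gene"),
    isoform = vapply(parsed, `[[`, character(1), "isoform"),
    mutation_type = df$mutation_type,
    disease = df$disease,
    pathway = df$pathway,
    stringsAsFactors = FALSE)
  out$cosmic_ids <- cosmic
  out[, c("display_name", "token", "gene", "isoform", "cosmic_ids",
          "mutation_type", "disease", "pathway")]
}

#' Read the therapeutic corpus
#'
#' Reads a therapeutic table (`therapeutic`, `reference_id`, `specificity`,
#' `pathway` plus the fixture-added `binding_mode` column) into
#' [therapeutic()] objects. The literal reference id
#' `"Recombinant antibody"` marks antibodies; everything else is a small
#' molecule. Specificity cells split on `","`. Binding modes for the
#' small-molecule inhibitors are curator-supplied annotations, not part of
#' the published table.
#'
#' @param path TSV path; defaults to the bundled transcription of the
#'   published therapeutic corpus (39 small molecules + 2 antibodies).
#' @return List of [therapeutic()]s.
#' @export
read_therapeutic_table <- function(path = default_therapeutic_table()) {
  df <- read_tsv_checked(path, c("therapeutic", "reference_id",
                                 "specificity", "pathway", "binding_mode"))
  lapply(seq_len(nrow(df)), function(i) {
    ref <- trimws(df$reference_id[i])
    kind <- if (identical(ref, "Recombinant antibody"))
      "recombinant_antibody" else "small_molecule"
    therapeutic(
      name = df$therapeutic[i], kind = kind, reference_id = ref,
      specificity = trimws(strsplit(df$specificity[i], ",",
                                    fixed = TRUE)[[1]]),
      binding_mode = df$binding_mode[i],
      pathway_name = df$pathway[i])
  })
}

# ---- synthetic reference generation ---------------------------------------

# Wild-type residue demands implied by a spec list, as (coordinate, residue)
# pairs; coordinates with no stated residue contribute only to the length.
spec_constraints <- function(specs) {
  coords <- integer(); res <- character(); maxc <- 0L
  add <- function(pos, aa) {
    maxc <<- max(maxc, pos)
    if (!is.na(aa)) { coords <<- c(coords, pos); res <<- c(res, aa) }
  }
  for (s in specs) {
    switch(mod_type(s),
      replaced_residue = add(s$coordinate, s$from_aa),
      fragment_deletion = {
        add(s$range$start, s$flank_first)
        add(s$range$end, s$flank_last)
      },
      fragment_insertion = {
        if (!is.na(s$left_flank)) add(s$position - 1L, s$left_flank)
        if (!is.na(s$right_flank)) add(s$position, s$right_flank)
        maxc <- max(maxc, s$position)
      },
      truncation = add(s$new_end + 1L, s$stop_residue),
      frameshift = add(s$position, s$ref_residue),
      NULL)
  }
  list(coords = coords, residues = res, max_coord = maxc)
}

#' Generate synthetic reference sequences consistent with a variant corpus
#'
#' For every gene (+ isoform) in `records`, emits a deterministic
#' pseudo-random protein sequence long enough to cover the gene's maximum
#' variant coordinate plus ten residues, with the stated wild-type residue
#' placed at every stated coordinate (e.g. `L` at EGFR 858). Genes that
#' carry no coordinates (fusion partners) receive a sequence of
#' `default_length`. Two genes demanding different residues at the same
#' coordinate make the corpus internally inconsistent and raise an error
#' listing the conflict. The same seed always yields byte-identical output.
#'
#' These synthetic sequences stand in for database reference sequences so
#' that every variant in the corpus can be applied without network access;
#' they are random except at the constrained coordinates.
#'
#' @param records variant record data frame ([read_variant_table()]).
#' @param seed integer seed for the pseudo-random residues.
#' @param default_length sequence length for genes without coordinate
#'   constraints.
#' @param aliases alias registry for token parsing.
#' @return Named list of [reference_sequence()]s keyed by accession
#'   (`SYN_<GENE><isoform>`).
#' @export
generate_fixture_references <- function(records, seed = 42L,
                                        default_length = 600L,
                                        aliases = load_alias_registry()) {
  stopifnot(is.data.frame(records))
  demands <- list()  # key -> list(gene, isoform, coords, residues, max)
  note <- function(gene, isoform, cons) {
    key <- paste0(gene, if (is.na(isoform)) "" else isoform)
    d <- demands[[key]] %||% list(gene = gene, isoform = isoform,
                                  coords = integer(), residues = character(),
                                  max_coord = 0L)
    d$coords <- c(d$coords, cons$coords)
    d$residues <- c(d$residues, cons$residues)
    d$max_coord <- max(d$max_coord, cons$max_coord)
    demands[[key]] <<- d
  }
  for (i in seq_len(nrow(records))) {
    p <- parse_variant_token(records$token[i], aliases = aliases)
    if (p$is_fusion) {
      note(p$gene, NA_character_, list(coords = integer(),
                                       residues = character(), max_coord = 0L))
      note(p$fusion_partner, NA_character_,
           list(coords = integer(), residues = character(), max_coord = 0L))
    } else {
      note(p$gene, p$isoform, spec_constraints(p$specs))
    }
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  refs <- list()
  for (key in sort(names(demands))) {
    d <- demands[[key]]
    # detect conflicting residue demands before placement
    if (length(d$coords)) {
      tab <- split(d$residues, d$coords)
      for (co in names(tab)) {
        u <- unique(tab[[co]])
        if (length(u) > 1L)
          stop("conflicting wild-type residues for ", key,
               " at coordinate ", co, ": ", paste(u, collapse = " vs "))
      }
    }
    len <- max(d$max_coord + 10L, if (d$max_coord == 0L) default_length else 0L)
    chars <- sample(.aa_alphabet(), len, replace = TRUE)
    if (length(d$coords)) chars[d$coords] <- d$residues
    refs[[paste0("SYN_", key)]] <- reference_sequence(
      accession = paste0("SYN_", key), gene = d$gene, isoform = d$isoform,
      residues = paste(chars, collapse = ""))
  }
  refs
}

#' Build a variant entity from a corpus record
#'
#' Parses the record's token, attaches Disease Ontology terms matched from
#' the record's disease text and the COSMIC cross-references, and anchors
#' the entity on the given reference sequence (or, if none is supplied, on
#' a nominal range covering the variant coordinates plus ten residues).
#' Fusion records yield an entity with no modifications; breakpoints must
#' be supplied through [build_fusion()].
#'
#' @param record one-row data frame from [read_variant_table()].
#' @param refs named list of [reference_sequence()]s keyed by accession, or
#'   `NULL`.
#' @param terms disease-term mapping ([load_disease_terms()]).
#' @param aliases alias registry.
#' @return A [variant_entity()].
#' @export
variant_record_to_entity <- function(record, refs = NULL,
                                     terms = load_disease_terms(),
                                     aliases = load_alias_registry()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  p <- parse_variant_token(record$token, aliases = aliases)
  key <- paste0(p$gene, if (is.na(p$isoform)) "" else p$isoform)
  accession <- paste0("SYN_", key)
  end <- if (!is.null(refs) && accession %in% names(refs)) {
    seq_len_aa(refs[[accession]])
  } else {
    max(spec_constraints(p$specs)$max_coord + 10L, 10L)
  }
  variant_entity(
    gene = p$gene, isoform = p$isoform, reference_accession = accession,
    ref_range = sequence_range(1L, end), modifications = p$specs,
    display_name = record$token,
    diseases = match_disease_terms(record$disease, terms = terms),
    cosmic_ids = record$cosmic_ids[[1]],
    pathway_name = record$pathway)
}

# ---- JSON model export/import ---------------------------------------------

entity_to_list <- function(e) {
  list(gene = e$gene, isoform = e$isoform,
       reference_accession = e$reference_accession,
       ref_range = list(start = e$ref_range$start, end = e$ref_range$end),
       modifications = lapply(e$modifications, mod_to_list),
       display_name = e$display_name,
       diseases = lapply(e$diseases, function(t)
         list(do_id = t$do_id, name = t$name, ncit_xref = t$ncit_xref)),
       cosmic_ids = as.list(e$cosmic_ids),
       pathway_name = e$pathway_name)
}

entity_from_list <- function(x, where) {
  need <- function(field) {
    if (is.null(x[[field]]))
      stop("model validation error at ", where, "/", field,
           ": required field missing")
    x[[field]]
  }
  rr <- need("ref_range")
  as_chr <- function(v) if (is.null(v) || length(v) == 0L || is.na(v))
    NA_character_ else as.character(v)
  variant_entity(
    gene = need("gene"), isoform = as_chr(x$isoform),
    reference_accession = need("reference_accession"),
    ref_range = sequence_range(rr$start, rr$end),
    modifications = lapply(x$modifications %||% list(), mod_from_list),
    display_name = need("display_name"),
    diseases = lapply(x$diseases %||% list(), function(t)
      disease_term(t$do_id, t$name, ncit_xref = as_chr(t$ncit_xref))),
    cosmic_ids = vapply(x$cosmic_ids %||% list(), as.character, character(1)),
    pathway_name = x$pathway_name %||% "")
}

therapeutic_to_list <- function(t) {
  list(name = t$name, kind = t$kind, reference_id = t$reference_id,
       specificity = as.list(t$specificity), binding_mode = t$binding_mode,
       pathway_name = t$pathway_name)
}

therapeutic_from_list <- function(x, where) {
  for (field in c("name", "kind", "reference_id", "specificity",
                  "binding_mode"))
    if (is.null(x[[field]]))
      stop("model validation error at ", where, "/", field,
           ": required field missing")
  therapeutic(name = x$name, kind = x$kind, reference_id = x$reference_id,
              specificity = vapply(x$specificity, as.character, character(1)),
              binding_mode = x$binding_mode,
              pathway_name = x$pathway_name %||% "")
}

#' Export and import the full model as a JSON document
#'
#' `export_model()` writes variant entities, pathway graphs and
#' therapeutics into a single JSON document (the package's published model
#' dialect; see `inst/schema/model.schema.json`). `import_model()` reads it
#' back, validating structure as it goes; a malformed document raises a
#' validation error naming the offending JSON path. The round trip is
#' lossless.
#'
#' @param entities list of [variant_entity()]s.
#' @param graphs list of [pathway_graph()]s.
#' @param therapeutics list of [therapeutic()]s.
#' @param path JSON file path.
#' @return `export_model()` returns `path` invisibly; `import_model()`
#'   returns a list with `entities`, `graphs`, `therapeutics`.
#' @export
export_model <- function(path, entities = list(), graphs = list(),
                         therapeutics = list()) {
  doc <- list(
    format = "pathvar-model",
    version = 1L,
    entities = lapply(entities, entity_to_list),
    graphs = lapply(graphs, graph_to_list),
    therapeutics = lapply(therapeutics, therapeutic_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname export_model
#' @export
import_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("model validation error at /: not parseable JSON (",
                         conditionMessage(e), ")"))
  if (!identical(doc$format, "pathvar-model"))
    stop("model validation error at /format: expected 'pathvar-model'")
  list(
    entities = lapply(seq_along(doc$entities %||% list()), function(i)
      entity_from_list(doc$entities[[i]], paste0("/entities/", i - 1L))),
    graphs = lapply(doc$graphs %||% list(), graph_from_list),
    therapeutics = lapply(seq_along(doc$therapeutics %||% list()), function(i)
      therapeutic_from_list(doc$therapeutics[[i]],
                            paste0("/therapeutics/", i - 1L))))
}
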