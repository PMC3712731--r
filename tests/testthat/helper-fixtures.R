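# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

random_residues <- function(n) {
  paste(sample(setdiff(amino_acids()$one, "X"), n, replace = TRUE),
        collapse = "")
}

random_ref <- function(n, gene = "TOY", accession = paste0("SYN_", gene)) {
  reference_sequence(accession, gene, random_residues(n))
}

# Independent character-editing oracle: applies replacements, deletions and
# insertions by plain substring surgery, right-to-left so that left-hand
# coordinates stay valid. Assumes modification sites do not overlap or touch.
naive_apply <- function(residues, specs) {
  anchor <- vapply(specs, function(s) switch(class(s)[[1]],
    replaced_residue = s$coordinate,
    fragment_deletion = s$range$start,
    fragment_insertion = s$position), integer(1))
  for (s in specs[order(anchor, decreasing = TRUE)]) {
    n <- nchar(residues)
    residues <- switch(class(s)[[1]],
      replaced_residue = {
        substr(residues, s$coordinate, s$coordinate) <- s$to_aa
        residues
      },
      fragment_deletion = paste0(
        substr(residues, 1L, s$range$start - 1L),
        substr(residues, s$range$end + 1L, n)),
      fragment_insertion = paste0(
        substr(residues, 1L, s$position - 1L), s$peptide,
        substr(residues, s$position, n)))
  }
  residues
}

# Random edit set over a sequence of length n: up to k modifications on
# disjoint, non-adjacent coordinate blocks (so the oracle is unambiguous).
random_edit_instance <- function(n = 50L, k = 5L) {
  ref <- random_ref(n)
  chars <- strsplit(ref$residues, "")[[1]]
  specs <- list()
  used_until <- 0L
  n_mods <- sample.int(k, 1L)
  for (i in seq_len(n_mods)) {
    start <- used_until + 2L + sample.int(3L, 1L)
    if (start > n - 2L) break
    kind <- sample(c("sub", "del", "ins"), 1L)
    if (kind == "sub") {
      to <- sample(setdiff(setdiff(amino_acids()$one, "X"), chars[start]), 1L)
      specs[[length(specs) + 1L]] <- replaced_residue(start, chars[start], to)
      used_until <- start
    } else if (kind == "del") {
      end <- min(start + sample.int(4L, 1L) - 1L, n - 1L)
      specs[[length(specs) + 1L]] <- fragment_deletion(
        sequence_range(start, end),
        flank_first = chars[start], flank_last = chars[end])
      used_until <- end
    } else {
      pep <- random_residues(sample.int(4L, 1L))
      specs[[length(specs) + 1L]] <- fragment_insertion(
        start, peptide = pep,
        left_flank = chars[start - 1L], right_flank = chars[start])
      used_until <- start
    }
  }
  entity <- variant_entity("TOY", ref$accession, sequence_range(1L, n),
                           modifications = specs, display_name = "toy")
  list(ref = ref, entity = entity, specs = specs)
}

# Toy graph of Fig-4 shape: a wild-type receptor and a mutant receptor, one
# normal event, one disease event, nested pathways sub (P2) inside top (P1).
toy_disease_graph <- function(tagged = TRUE) {
  g <- pathway_graph(
    entities = list(
      list(id = "egf", name = "EGF"),
      list(id = "egfr", name = "EGFR"),
      list(id = "egfr_viii", name = "EGFRvIII"),
      list(id = "egfr_p", name = "phospho-EGFR")),
    events = list(
      list(id = "bind", name = "EGF binds EGFR",
           inputs = c("egf", "egfr"), outputs = "egfr_p"),
      list(id = "mut_act", name = "constitutive EGFRvIII activation",
           inputs = "egfr_viii", outputs = "egfr_viii")),
    pathways = list(
      list(id = "p1", name = "Signaling by EGFR", events = character()),
      list(id = "p2", name = "EGFR activation", events = c("bind", "mut_act"),
           parent = "p1")))
  if (tagged)
    g <- tag_entity(g, "egfr_viii",
                    disease_term(3075, "adult glioblastoma multiforme"))
  g
}

# Random small pathway graph, optionally with random disease tags.
random_graph <- function(n_ent = 6L, n_ev = 4L, tag_prob = 0.3) {
  ents <- lapply(seq_len(n_ent), function(i)
    list(id = paste0("e", i), name = paste0("entity ", i)))
  evs <- lapply(seq_len(n_ev), function(i) {
    parts <- sample(paste0("e", seq_len(n_ent)), sample(2:3, 1L))
    list(id = paste0("r", i), name = paste0("reaction ", i),
         inputs = parts[1], outputs = parts[-1])
  })
  pws <- list(
    list(id = "top", name = "top pathway", events = character()),
    list(id = "sub", name = "sub pathway",
         events = paste0("r", seq_len(n_ev)), parent = "top"))
  g <- pathway_graph(ents, evs, pws)
  for (i in seq_len(n_ent)) {
    if (stats::runif(1) < tag_prob)
      g <- tag_entity(g, paste0("e", i), disease_term(i, paste0("disease ", i)))
  }
  g
}

all_node_tags <- function(g) {
  ids <- c(names(g$entities), names(g$events), names(g$pathways))
  stats::setNames(lapply(ids, function(id)
    sort(vapply(node_diseases(g, id), function(t) t$do_id, integer(1)))), ids)
}
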