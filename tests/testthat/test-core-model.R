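test_that("validate_entity reports violations as data, empty iff valid", {
  rr <- sequence_range(1, 724)
  plain <- variant_entity("PIK3R1", "SYN_PIK3R1", rr)
  expect_identical(validate_entity(plain), character(0))

  with_del <- variant_entity(
    "PIK3R1", "SYN_PIK3R1", rr,
    list(fragment_deletion(sequence_range(463, 466))))
  expect_identical(validate_entity(with_del), character(0))

  out_of_range <- variant_entity(
    "EGFR", "SYN_EGFR", sequence_range(1, 800),
    list(replaced_residue(900, "L", "R")))
  v <- validate_entity(out_of_range)
  expect_length(v, 1)
  expect_match(v, "900")
  expect_match(v, "outside")
})

test_that("validate_entity flags overlapping deletions and fusion-anchored insertions", {
  rr <- sequence_range(1, 100)
  overlapping <- variant_entity(
    "G", "A", rr,
    list(fragment_deletion(sequence_range(10, 20)),
         fragment_deletion(sequence_range(15, 30))))
  expect_match(validate_entity(overlapping), "overlapping")

  # insertion at end + 1 is the fusion append position, allowed
  fusion_like <- variant_entity(
    "BCR", "SYN_BCR", sequence_range(1, 584),
    list(fragment_insertion(585, source_accession = "SYN_FGFR1",
                            source_range = sequence_range(429, 822))))
  expect_identical(validate_entity(fusion_like), character(0))

  too_far <- variant_entity(
    "BCR", "SYN_BCR", sequence_range(1, 584),
    list(fragment_insertion(600, peptide = "AAA")))
  expect_match(validate_entity(too_far), "insertion")
})

test_that("validate_entity is idempotent and order-independent", {
  rr <- sequence_range(1, 200)
  mods <- list(
    replaced_residue(250, "L", "R"),              # out of range
    fragment_deletion(sequence_range(10, 20)),
    fragment_deletion(sequence_range(18, 30)),    # overlaps
    fragment_insertion(50, peptide = "NPG"))
  e1 <- variant_entity("G", "A", rr, mods)
  e2 <- variant_entity("G", "A", rr, rev(mods))
  expect_identical(validate_entity(e1), validate_entity(e1))
  expect_identical(validate_entity(e1), validate_entity(e2))
})

test_that("constructors enforce type invariants", {
  expect_error(sequence_range(5, 3), "start")
  expect_error(replaced_residue(858, "L", "L"), "differ")
  expect_error(replaced_residue(858, "B", "R"), "unknown")
  expect_error(fragment_insertion(10), "payload")
  expect_error(fragment_insertion(10, peptide = "NPG",
                                  source_accession = "X",
                                  source_range = sequence_range(1, 2)),
               "payload")
  expect_error(fragment_insertion(10, peptide = ""), "non-empty")
  expect_error(frameshift(795, -1), "tail_length")
  expect_error(disease_term(0, "x"), "positive")
  expect_error(disease_term(3075, ""), "non-empty")
  expect_error(therapeutic("ab", "recombinant_antibody", "Recombinant antibody",
                           "EGFR", binding_mode = "covalent"),
               "not_applicable")
  expect_error(therapeutic("d", "small_molecule", "ChEBI:1", character()),
               "specificity")
  expect_error(mutant_set("s", character(), "reversible_sensitive"),
               "member")
})

test_that("amino-acid one/three-letter mapping is bijective, X maps to Xaa", {
  tab <- amino_acids()
  std <- tab[tab$one != "X", ]
  expect_identical(aa_one(aa_three(std$one)), std$one)
  expect_identical(aa_three("X"), "Xaa")
  expect_false(anyDuplicated(tab$three) > 0)
  expect_true(all(nzchar(std$mod_term)))
})

test_that("every modification spec round-trips through JSON without loss", {
  specs <- list(
    replaced_residue(858, "L", "R"),
    fragment_deletion(sequence_range(463, 466),
                      flank_first = "Y", flank_last = "L"),
    fragment_insertion(771, peptide = "NPG",
                       left_flank = "D", right_flank = "N"),
    fragment_insertion(585, source_accession = "SYN_FGFR1",
                       source_range = sequence_range(429, 822)),
    fragment_insertion(746, peptide = "V", from_delins = TRUE),
    truncation(129, stop_residue = "R"),
    frameshift(795, 139),
    frameshift(764, 4, ref_residue = "L"))
  for (s in specs) {
    json <- jsonlite::toJSON(mod_to_list(s), auto_unbox = TRUE, null = "null",
                             na = "null")
    back <- mod_from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
    expect_equal(back, s, info = class(s)[[1]])
  }
})

test_that("pathway_graph rejects dangling references and containment cycles", {
  expect_error(pathway_graph(
    entities = list(list(id = "a", name = "A")),
    events = list(list(id = "r", name = "R", inputs = "ghost"))),
    "unknown entities")
  expect_error(pathway_graph(
    pathways = list(
      list(id = "p1", name = "P1", events = character(), parent = "p2"),
      list(id = "p2", name = "P2", events = character(), parent = "p1"))),
    "cycle")
})
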