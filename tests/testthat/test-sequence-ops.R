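test_that("apply_modifications handles the worked single-edit cases", {
  set.seed(11)
  # identity: no modifications
  ref <- random_ref(100, gene = "EGFR", accession = "SYN_EGFR")
  ent <- variant_entity("EGFR", "SYN_EGFR", sequence_range(1, 100))
  expect_identical(apply_modifications(ref, ent), ref$residues)

  # in-frame deletion of residues 463..466 from a 724-residue protein
  chars <- strsplit(random_residues(724), "")[[1]]
  chars[463] <- "Y"; chars[466] <- "L"
  ref <- reference_sequence("SYN_PIK3R1", "PIK3R1",
                            paste(chars, collapse = ""))
  ent <- variant_entity(
    "PIK3R1", "SYN_PIK3R1", sequence_range(1, 724),
    list(fragment_deletion(sequence_range(463, 466),
                           flank_first = "Y", flank_last = "L")))
  out <- apply_modifications(ref, ent)
  expect_identical(nchar(out), 720L)
  expect_identical(substr(out, 1, 462), substr(ref$residues, 1, 462))
  expect_identical(substr(out, 463, 720), substr(ref$residues, 467, 724))

  # missense: length preserved, stated position replaced
  chars <- strsplit(random_residues(900), "")[[1]]
  chars[858] <- "L"
  ref <- reference_sequence("SYN_EGFR", "EGFR", paste(chars, collapse = ""))
  ent <- variant_entity("EGFR", "SYN_EGFR", sequence_range(1, 900),
                        list(replaced_residue(858, "L", "R")))
  out <- apply_modifications(ref, ent)
  expect_identical(nchar(out), 900L)
  expect_identical(substr(out, 858, 858), "R")

  # stated wild-type residue must match the reference
  chars[858] <- "M"
  ref_bad <- reference_sequence("SYN_EGFR", "EGFR",
                                paste(chars, collapse = ""))
  expect_error(apply_modifications(ref_bad, ent),
               "858.*expected L.*found M")
})

test_that("conflicting modifications are rejected", {
  set.seed(12)
  ref <- random_ref(60)
  chars <- strsplit(ref$residues, "")[[1]]
  overlap <- variant_entity(
    "TOY", ref$accession, sequence_range(1, 60),
    list(fragment_deletion(sequence_range(10, 20)),
         fragment_deletion(sequence_range(15, 25))))
  expect_error(apply_modifications(ref, overlap), "overlap")
  inside_del <- variant_entity(
    "TOY", ref$accession, sequence_range(1, 60),
    list(fragment_deletion(sequence_range(10, 20)),
         replaced_residue(15, chars[15],
                          setdiff(c("A", "G"), chars[15])[1])))
  expect_error(apply_modifications(ref, inside_del), "conflict")
})

test_that("nonsense and frameshift yield truncated products", {
  set.seed(13)
  chars <- strsplit(random_residues(200), "")[[1]]
  chars[130] <- "R"
  ref <- reference_sequence("SYN_PTEN", "PTEN", paste(chars, collapse = ""))
  ent <- variant_entity("PTEN", "SYN_PTEN", sequence_range(1, 200),
                        list(truncation(129, stop_residue = "R")))
  expect_identical(apply_modifications(ref, ent),
                   substr(ref$residues, 1, 129))

  ref <- random_ref(150, gene = "FGFR2", accession = "SYN_FGFR2")
  ent <- variant_entity("FGFR2", "SYN_FGFR2", sequence_range(1, 150),
                        list(frameshift(100, 4)))
  out <- apply_modifications(ref, ent)
  expect_identical(nchar(out), 103L)  # 99 retained + 4 unknown tail residues
  expect_identical(substr(out, 100, 103), "XXXX")
})

test_that("build_fusion anchors the insertion at the truncated host end", {
  set.seed(14)
  host <- random_ref(600, gene = "BCR", accession = "SYN_BCR")
  insert <- random_ref(850, gene = "FGFR1", accession = "SYN_FGFR1")
  fus <- build_fusion(host, sequence_range(1, 584),
                      insert, sequence_range(429, 822))
  ins <- fus$entity$modifications[[1]]
  expect_identical(ins$position, 585L)
  expect_identical(ins$source_accession, "SYN_FGFR1")
  expect_identical(nchar(fus$residues), 978L)  # 584 + (822 - 429 + 1)
  expect_identical(fus$residues,
                   paste0(substr(host$residues, 1, 584),
                          substr(insert$residues, 429, 822)))
  expect_identical(fus$entity$display_name, "BCR-FGFR1")

  # toy case: host truncated at 2, three inserted residues -> length 5
  toy_host <- reference_sequence("H", "H", "ACDEF")
  toy_ins <- reference_sequence("I", "I", "GHIKL")
  toy <- build_fusion(toy_host, sequence_range(1, 2),
                      toy_ins, sequence_range(3, 5))
  expect_identical(toy$residues, "ACIKL")
  expect_identical(nchar(toy$residues), 5L)
})

test_that("fusing a pre-truncated host equals truncating while fusing", {
  set.seed(15)
  host <- random_ref(300, gene = "H")
  insert <- random_ref(200, gene = "I", accession = "SYN_I")
  a <- build_fusion(host, sequence_range(1, 120),
                    insert, sequence_range(50, 180))
  pre <- reference_sequence(host$accession, host$gene,
                            substr(host$residues, 1, 120))
  b <- build_fusion(pre, sequence_range(1, 120),
                    insert, sequence_range(50, 180))
  expect_identical(a$residues, b$residues)
})

test_that("random edit sets agree with the character-editing oracle", {
  set.seed(16)
  for (i in 1:60) {
    inst <- random_edit_instance(n = 50L, k = 5L)
    got <- apply_modifications(inst$ref, inst$entity)
    expect_identical(got, naive_apply(inst$ref$residues, inst$specs),
                     info = paste("instance", i))
    # length algebra: deletions subtract, insertions add, substitutions keep
    dlen <- sum(vapply(inst$specs, function(s)
      if (inherits(s, "fragment_deletion"))
        s$range$end - s$range$start + 1L else 0L, integer(1)))
    ilen <- sum(vapply(inst$specs, function(s)
      if (inherits(s, "fragment_insertion")) nchar(s$peptide) else 0L,
      integer(1)))
    expect_identical(nchar(got), 50L - dlen + ilen)
  }
})

test_that("FASTA round trip preserves accession, gene, isoform and residues", {
  set.seed(17)
  refs <- list(random_ref(70, gene = "AAA", accession = "SYN_AAA"),
               reference_sequence("SYN_FGFR2b", "FGFR2", random_residues(130),
                                  isoform = "b"))
  names(refs) <- vapply(refs, `[[`, character(1), "accession")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_refs(refs, path)
  back <- read_fasta_refs(path)
  expect_equal(back, refs)
})
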