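drugs <- read_therapeutic_table()

test_that("the drug corpus reproduces the published counts", {
  expect_length(drugs, 41)
  expect_length(filter_therapeutics(drugs, kind = "small_molecule"), 39)
  ab <- filter_therapeutics(drugs, kind = "recombinant_antibody")
  expect_setequal(vapply(ab, `[[`, character(1), "name"),
                  c("Cetuximab", "GP369"))
  expect_length(filter_therapeutics(
    drugs, pathway = "Signaling by EGFR in Cancer",
    kind = "small_molecule", target_includes = "EGFR"), 9)
  expect_length(filter_therapeutics(drugs, target_includes = "HSP90"), 5)
  expect_length(filter_therapeutics(
    drugs, kind = "small_molecule", target_includes = "FGFR"), 12)
  expect_length(filter_therapeutics(drugs, target_includes = "PI3K"), 10)
  expect_length(filter_therapeutics(drugs, target_includes = "AKT"), 3)
})

test_that("filtering by a conjunction equals intersecting single predicates", {
  name_of <- function(rows) vapply(rows, `[[`, character(1), "name")
  combos <- list(
    list(pathway = "Signaling by EGFR in Cancer", kind = "small_molecule"),
    list(kind = "small_molecule", target_includes = "EGFR"),
    list(pathway = "Signaling by FGFR in Disease",
         target_includes = "VEGFR"))
  for (combo in combos) {
    joint <- name_of(do.call(filter_therapeutics, c(list(drugs), combo)))
    singles <- lapply(names(combo), function(arg)
      name_of(do.call(filter_therapeutics,
                      c(list(drugs), combo[arg]))))
    expect_setequal(joint, Reduce(intersect, singles))
  }
  # exclusion is the complement within the included set
  only_egfr <- filter_therapeutics(drugs, target_includes = "EGFR",
                                   target_excludes = "ERBB2")
  expect_false(any(grepl("Lapatinib|Afatinib|HKI-272|Canertinib",
                         name_of(only_egfr))))
})

test_that("target coverage understands family designators and isoforms", {
  expect_true(target_covers("EGFR", "Pan-ERBB"))
  expect_true(target_covers("EGFR", "EGFR"))
  expect_false(target_covers("EGFR", "ERBB2"))
  expect_false(target_covers("EGFR", "VEGFR"))
  expect_true(target_covers("FGFR", "FGFR3"))
  expect_true(target_covers("FGFR", "FGFR2b"))
  expect_true(target_covers("FGFR", "Pan-FGFR"))
  expect_true(target_covers("PI3K", "PIK3CA"))
  expect_true(target_covers("PI3K", "PI3K Class I"))
  expect_false(target_covers("FGFR", "VEGFR"))  # no substring false positive
})

test_that("TKIs classify by spectrum and reversibility", {
  by_name <- function(n) Filter(function(t) t$name == n, drugs)[[1]]
  expect_identical(classify_tki(by_name("Gefitinib"), "EGFR"),
                   "specific_reversible")
  expect_identical(classify_tki(by_name("Erlotinib"), "EGFR"),
                   "specific_reversible")
  expect_identical(classify_tki(by_name("Afatinib"), "EGFR"),
                   "broad_irreversible")
  # Vandetanib hits VEGFR besides EGFR: broad spectrum ("EGFRplus")
  expect_match(classify_tki(by_name("Vandetanib"), "EGFR"), "^broad")
  expect_identical(classify_tki(by_name("WZ4002"), "EGFR"),
                   "specific_irreversible")
  expect_error(classify_tki(by_name("Gefitinib"), "FGFR"), "target")
  expect_error(classify_tki(by_name("Cetuximab"), "EGFR"), "small molecule")

  synthetic <- therapeutic("toy", "small_molecule", "Pending",
                           c("EGFR", "ERBB2"), binding_mode = "covalent")
  expect_identical(classify_tki(synthetic, "EGFR"), "broad_irreversible")
})

test_that("classification is total over the corpus small molecules", {
  anchors <- c("EGFR", "HSP90", "FGFR", "PI3K", "AKT", "mTOR")
  for (t in filter_therapeutics(drugs, kind = "small_molecule")) {
    anchor <- anchors[vapply(anchors, function(a)
      any(vapply(t$specificity, function(tok) target_covers(a, tok),
                 logical(1))), logical(1))][1]
    expect_true(classify_tki(t, anchor) %in%
                  c("specific_reversible", "specific_irreversible",
                    "broad_reversible", "broad_irreversible"),
                info = t$name)
  }
})

test_that("mutant-set sensitivity follows the reversibility rules", {
  rev_tki <- therapeutic("reversible TKI", "small_molecule", "Pending",
                         "EGFR", binding_mode = "non_covalent")
  irrev_tki <- therapeutic("irreversible TKI", "small_molecule", "Pending",
                           "EGFR", binding_mode = "covalent")
  antibody <- therapeutic("antibody", "recombinant_antibody",
                          "Recombinant antibody", "EGFR",
                          binding_mode = "not_applicable")
  expect_identical(sensitivity_lookup("reversible_sensitive", rev_tki),
                   "inhibited")
  expect_identical(sensitivity_lookup("reversible_resistant", rev_tki),
                   "not_inhibited")
  expect_identical(sensitivity_lookup("reversible_resistant", irrev_tki),
                   "inhibited")
  # covalent TKIs inhibit the wild-type receptor as well
  expect_identical(sensitivity_lookup("wild_type_overexpressed", irrev_tki),
                   "inhibited")
  expect_identical(sensitivity_lookup("wild_type_overexpressed", antibody),
                   "inhibited")
  expect_identical(sensitivity_lookup("reversible_sensitive", antibody),
                   "unknown")
  expect_identical(sensitivity_lookup("wild_type_overexpressed", rev_tki),
                   "unknown")
  # accepts a mutant_set object directly
  ms <- mutant_set("resistant EGFR mutants", "EGFR T790M",
                   "reversible_resistant")
  expect_identical(sensitivity_lookup(ms, irrev_tki), "inhibited")
})

test_that("a covalent TKI is never reported not_inhibited for any mutant set", {
  classes <- c("reversible_sensitive", "reversible_resistant",
               "wild_type_overexpressed")
  covalent <- Filter(function(t) t$binding_mode == "covalent",
                     filter_therapeutics(drugs, target_includes = "EGFR"))
  expect_gt(length(covalent), 0)
  for (t in covalent) {
    for (cl in classes) {
      expect_false(sensitivity_lookup(cl, t) == "not_inhibited",
                   info = paste(t$name, cl))
    }
  }
})
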