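lib <- load_library()

test_that("diagnostic classification reproduces the reference cleavage cases", {
  # chebulagic acid: chebuloyl + HHDP + galloyl ions nest to the chebulic class
  res <- classify_spectrum(c(300.9990, 275.0198, 205.0504, 337.0199, 169.0144,
                             463.0513, 633.0724), precursor_mz = 953.0911)
  expect_equal(res$class, "chebulic ellagitannin")
  expect_true("chebuloyl_direct" %in% res$fired)
  # corilagin: HHDP without chebuloyl
  expect_equal(classify_spectrum(c(300.9996, 275.0202, 463.0517, 169.0144),
                                 precursor_mz = 633.0739)$class,
               "ellagitannin")
  # tri-galloyl-glucose: galloyl ions with galloylglucose core ions
  expect_equal(classify_spectrum(c(169.0144, 313.0567, 211.0243, 465.0668,
                                   271.0461), precursor_mz = 635.0888)$class,
               "gallotannin")
  # gallic acid: galloyl ions alone at a small precursor
  expect_equal(classify_spectrum(c(125.0244, 169.0143, 79.0184),
                                 precursor_mz = 169.0145)$class,
               "phenolcarboxylic acid")
  # triterpenoid-like fragments fire nothing
  expect_equal(classify_spectrum(c(487.3423, 299.9897),
                                 precursor_mz = 487.3433)$class,
               "unclassified")
  expect_error(classify_spectrum(c(169.0), rules = list()), "empty rule set")
})

test_that("rule priority is total and the fired class is order-independent", {
  rules <- default_diagnostic_rules()
  prio <- vapply(rules, `[[`, integer(1), "priority")
  expect_false(anyDuplicated(prio) > 0)
  set.seed(11)
  for (i in sample(nrow(lib), 25)) {
    shuffled <- sample(rules)
    expect_identical(
      classify_spectrum(lib$fragments[[i]], rules,
                        precursor_mz = lib$observed_mz[i])$class,
      classify_spectrum(lib$fragments[[i]], shuffled,
                        precursor_mz = lib$observed_mz[i])$class)
  }
})

test_that("chebuloyl soundness holds: the chebulic class only ever arises
           from a chebuloyl-family rule", {
  cheb_rules <- c("chebuloyl_direct", "chebuloyl_cascade", "chebulic_ester")
  # over the whole library
  for (i in seq_len(nrow(lib))) {
    res <- classify_spectrum(lib$fragments[[i]],
                             precursor_mz = lib$observed_mz[i])
    if (res$class == "chebulic ellagitannin") {
      expect_true(res$fired[1] %in% cheb_rules)
    }
  }
  # and under fuzzing with random fragment sets
  set.seed(23)
  for (k in 1:200) {
    fr <- sort(runif(sample(3:10, 1), 60, 1000))
    res <- classify_spectrum(fr, precursor_mz = runif(1, 150, 1100))
    if (res$class == "chebulic ellagitannin") {
      expect_true(res$fired[1] %in% cheb_rules)
    }
  }
})

test_that("marker invariants hold on the printed fragment lists", {
  tannic <- tannic_subset(lib)
  for (i in seq_len(nrow(tannic))) {
    fr <- tannic$fragments[[i]]
    cls <- classify_spectrum(fr, precursor_mz = tannic$observed_mz[i])$class
    if (any(abs(fr - 337.02) <= 0.01)) {
      expect_equal(cls, "chebulic ellagitannin",
                   label = paste("record", tannic$id[i]))
    } else if (any(abs(fr - 300.999) <= 0.01) &&
               !any(abs(fr - 351.0357) <= 0.01) &&
               !any(abs(fr - 365.0514) <= 0.01) &&
               !(any(abs(fr - c(275.0200)) <= 0.01) ||
                 any(abs(fr - c(293.0303)) <= 0.01)) ) {
      expect_equal(cls, "ellagitannin", label = paste("record", tannic$id[i]))
    }
  }
})

test_that("rules survive a JSON round-trip", {
  path <- tempfile(fileext = ".json")
  write_rules(default_diagnostic_rules(), path)
  back <- read_rules(path)
  expect_equal(length(back), length(default_diagnostic_rules()))
  r95 <- lib[lib$id == 95, ]
  expect_equal(classify_spectrum(r95$fragments[[1]], back,
                                 precursor_mz = r95$observed_mz)$class,
               "chebulic ellagitannin")
})

test_that("homolog inference recognises the methylation series", {
  h1 <- infer_homolog(355.031, 369.047)
  expect_equal(h1$name[1], "methylation")
  expect_equal(h1$multiplicity[1], 1L)
  h2 <- infer_homolog(683.110, 697.126)
  expect_equal(h2$name[1], "methylation")
  expect_equal(h2$multiplicity[1], 1L)
  expect_equal(nrow(infer_homolog(355.031, 355.031)), 0L)
})

test_that("CCS comparison matches, flags and skips as specified", {
  m <- compare_ccs(172.066, 170.416)
  expect_equal(m$status, "match")
  expect_equal(m$relative_deviation, 0.968, tolerance = 1e-3)
  f <- compare_ccs(301.139, 274.834)
  expect_equal(f$status, "flagged")
  expect_equal(f$relative_deviation, 9.571, tolerance = 1e-3)
  expect_equal(compare_ccs(NA, 170)$status, "not_evaluated")
  expect_error(compare_ccs(-1, 170), "positive")
  # scale invariance
  for (c_mult in c(0.5, 2, 10)) {
    expect_equal(compare_ccs(172.066 * c_mult, 170.416 * c_mult)$status,
                 "match")
    expect_equal(compare_ccs(301.139 * c_mult, 274.834 * c_mult)$status,
                 "flagged")
  }
})

test_that("evidence integration follows the stated precedence", {
  feature <- list(spectrum_id = "f1", precursor_mz = 953.0911, rt = 25)
  hit95 <- lib[lib$id == 95, ]
  hit95$ppm_deviation <- 0.1
  hit95$rank <- 1L
  # concordant standard hit + rule
  res <- integrate_evidence(feature, hit95,
                            rule_class = "chebulic ellagitannin")
  expect_equal(res$assigned_class, "chebulic ellagitannin")
  expect_setequal(res$evidence_flags, c("standard", "library", "diagnostic"))
  expect_false(res$conflict)
  # rule beats network when they disagree, with a conflict flag
  res2 <- integrate_evidence(feature, NULL, network_class = "ellagitannin",
                             rule_class = "gallotannin")
  expect_equal(res2$assigned_class, "gallotannin")
  expect_true(res2$conflict)
  # homolog-only lineage falls back to the parent's class
  homs <- data.frame(name = "methylation", multiplicity = 1L,
                     expected_delta = 14.01565, residual = -0.0004,
                     parent_id = 3L, parent_name = "chebulic acid",
                     parent_class = "phenolcarboxylic acid")
  res3 <- integrate_evidence(list(spectrum_id = "f2", precursor_mz = 369.047,
                                  rt = NA), homologs = homs)
  expect_equal(res3$assigned_class, "phenolcarboxylic acid")
  expect_equal(res3$evidence_flags, "homolog")
  # no evidence at all is an error
  expect_error(integrate_evidence(list(spectrum_id = "f3")), "no evidence")
})

test_that("the full pipeline annotates fixture spectra and stays quiet on
           decoys", {
  recs <- lib[lib$id %in% c(12, 56, 68, 80, 95, 107, 110), ]
  gen <- generate_spectra(recs, n_decoys = 10, fragment_noise_sd = 0.002,
                          seed = 9)
  run <- annotate_run(gen$spectra)
  expect_equal(nrow(run$results), 17L)
  islib <- startsWith(run$results$spectrum_id, "LIB-")
  got <- run$results$top_id[islib][order(run$results$spectrum_id[islib])]
  expect_equal(got, sort(recs$id))
  # decoys: no library hits, overwhelmingly unclassified
  dec <- run$results[!islib, ]
  expect_true(all(is.na(dec$top_id)))
  expect_gte(mean(dec$assigned_class == "unclassified"), 0.8)
  # the class-count summary agrees with the per-feature table
  expect_equal(sum(run$summary), 17L)
  expect_equal(unname(run$summary[["chebulic ellagitannin"]]),
               sum(run$results$assigned_class == "chebulic ellagitannin"))
  # TSV export is readable
  path <- tempfile(fileext = ".tsv")
  write_annotations(run, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 17L)
})

test_that("an empty spectrum list yields an empty result and summary", {
  run <- annotate_run(list())
  expect_equal(nrow(run$results), 0L)
  expect_equal(sum(run$summary), 0L)
})
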