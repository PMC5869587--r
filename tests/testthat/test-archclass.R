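test_that("device-set lookup reproduces the architecture table", {
  expect_equal(architecture_label(character(), "CAAX"), "A")
  expect_equal(architecture_label("PX", "CAAX"), "B")
  expect_equal(architecture_label("FYVE", "CAAX"), "C")
  expect_equal(architecture_label(c("FYVE", "MYR", "PALM_N"), character()), "D")
  expect_equal(architecture_label(c("FYVE", "MYR"), character()), "E")
  expect_equal(architecture_label("FYVE", character()), "F")
  expect_equal(architecture_label(c("MYR", "PALM_N"), character()), "G")
  expect_equal(architecture_label("MYR", character()), "H")
  expect_equal(architecture_label("PALM_N", "CAAX"), "I")
  expect_equal(architecture_label("MYR", c("CAAX", "PALM_C")), "J")
  expect_equal(architecture_label(character(), c("CAAX", "PALM_C")), "J")
  expect_equal(architecture_label("FYVE", "TM"), "K")
  expect_equal(architecture_label(character(), "TM"), "K")
  expect_equal(architecture_label(character(), "WMOTIF"), "L")
  expect_equal(architecture_label(character(), character()), "UNANCHORED")
  expect_equal(architecture_label(c("PX", "FYVE"), "CAAX"), "UNCLASSIFIED")
})

test_that("classification is total and deterministic over all device-set combinations", {
  n_dev <- c("PX", "FYVE", "MYR", "PALM_N")
  c_dev <- c("CAAX", "PALM_C", "TM", "WMOTIF")
  labels <- character(0)
  valid <- c(LETTERS[1:12], "UNANCHORED", "UNCLASSIFIED")
  for (ni in 0:15) {
    for (ci in 0:15) {
      ns <- n_dev[bitwAnd(bitwShiftR(ni, 0:3), 1) == 1]
      cs <- c_dev[bitwAnd(bitwShiftR(ci, 0:3), 1) == 1]
      lab <- architecture_label(ns, cs)
      expect_length(lab, 1)
      expect_true(lab %in% valid)
      labels <- c(labels, lab)
    }
  }
  # every class except the purely-exemplar ones is reachable
  expect_true(all(LETTERS[1:12] %in% labels))
  expect_true("UNANCHORED" %in% labels)
  # order of devices within a set never matters
  expect_equal(architecture_label(c("MYR", "FYVE"), character()),
               architecture_label(c("FYVE", "MYR"), character()))
})

test_that("all twelve planted exemplars round-trip through the classifier at mutation rate 0", {
  ex <- rheb_exemplars(seed = 17)
  res <- annotate_set(ex$proteins)
  truth <- vapply(ex$truths, function(t) t$class_label, "")
  expect_equal(res$table$class_label, unname(truth[res$table$id]))
  # device sets match the planted ground truth too
  for (id in res$table$id) {
    ann <- res$annotations[[id]]
    expect_setequal(ann$call$n_devices, ex$truths[[id]]$n_devices)
    expect_setequal(ann$call$c_devices, ex$truths[[id]]$c_devices)
  }
})

test_that("mutated exemplars still classify correctly (regression guard)", {
  hits <- 0L
  total <- 0L
  for (seed in 1:50) {
    ex <- rheb_exemplars(seed, mutation_rate = 0.02)
    res <- annotate_set(ex$proteins)
    truth <- vapply(ex$truths, function(t) t$class_label, "")
    hits <- hits + sum(res$table$class_label == unname(truth[res$table$id]))
    total <- total + 12L
  }
  expect_gte(hits / 50, 11)
  expect_equal(total, 600L)
})

test_that("a bare Rheb-like scaffold is UNANCHORED, a non-Rheb protein UNCLASSIFIED", {
  sc <- make_scaffold(3)
  ann <- annotate_protein(sc$record$sequence)
  expect_equal(classify(ann)$class_label, "UNANCHORED")
  # remove the diagnostic arginine: still has devices' worth of G boxes but
  # is no longer Rheb-like
  seq <- sc$record$sequence
  arg <- sc$truth$motifs$start[sc$truth$motifs$name == "DIAG_R"]
  substr(seq, arg, arg) <- "K"
  ann2 <- annotate_protein(seq)
  expect_equal(classify(ann2)$class_label, "UNCLASSIFIED")
})

test_that("distinct N-terminal configuration counting collapses duplicates", {
  ex <- rheb_exemplars(seed = 17, classes = c("C", "D", "E", "F", "G", "H"))
  res <- annotate_set(ex$proteins)
  calls <- lapply(res$annotations, function(a) a$call)
  # C and F share the FYVE-only configuration, so six classes give five sets
  expect_equal(count_distinct_n_terminal_configs(calls), 5)
  # duplicates collapse
  a1 <- classify(annotate_protein(plant_architecture("A", 1)$record$sequence))
  a2 <- classify(annotate_protein(plant_architecture("A", 2)$record$sequence))
  expect_equal(count_distinct_n_terminal_configs(list(a1, a2)), 1)
  expect_equal(count_distinct_n_terminal_configs(list()), 0)
})

test_that("configuration counting matches a naive set-of-sets oracle on random device sets", {
  withr::local_seed(31)
  n_dev <- c("PX", "FYVE", "MYR", "PALM_N")
  for (rep in 1:20) {
    calls <- lapply(1:12, function(i) {
      list(n_devices = sample(n_dev, sample(0:4, 1)), c_devices = character())
    })
    keys <- unique(vapply(calls, function(x)
      paste(sort(x$n_devices), collapse = "|"), ""))
    expect_equal(count_distinct_n_terminal_configs(calls), length(keys))
  }
})

test_that("lipid-modification typing distinguishes the three acyl/prenyl classes", {
  # triple-modified apusomonad-style exemplar: myristoylation +
  # C-terminal palmitoylation + prenylation
  j <- plant_architecture("J", seed = 1, j_palm_count = 2, j_myr = TRUE)
  ann <- annotate_protein(j$record$sequence)
  expect_setequal(lipid_modification_types(ann),
                  c("prenylation", "myristoylation", "palmitoylation"))
  # conventional Rheb: prenylation only
  a <- plant_architecture("A", seed = 1)
  expect_equal(lipid_modification_types(annotate_protein(a$record$sequence)),
               "prenylation")
  # FYVE-only euglenozoan form: no lipid modification at all
  f <- plant_architecture("F", seed = 1)
  expect_length(lipid_modification_types(annotate_protein(f$record$sequence)), 0)
})

test_that("class J variants cover both known members", {
  # Thecamonas-style: two pre-CaaX cysteines plus myristoylation
  j2 <- plant_architecture("J", seed = 1, j_palm_count = 2, j_myr = TRUE)
  ann2 <- annotate_protein(j2$record$sequence)
  expect_equal(sum(ann2$palm$predicted & ann2$palm$region == "C_TERMINAL"), 2)
  expect_true(ann2$myr$predicted)
  expect_equal(classify(ann2)$class_label, "J")
  # Amastigomonas-style: one cysteine, no myristoylation
  j1 <- plant_architecture("J", seed = 1, j_palm_count = 1, j_myr = FALSE)
  ann1 <- annotate_protein(j1$record$sequence)
  expect_equal(sum(ann1$palm$predicted & ann1$palm$region == "C_TERMINAL"), 1)
  expect_false(ann1$myr$predicted)
  expect_equal(classify(ann1)$class_label, "J")
})
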