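# RING domain location, subtype classification, annotation parsing and
# release reconciliation.

test_that("domain table parser keeps well-formed rows and flags foreign databases", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("AT1G01010.1", "md5", "300", "Pfam", "PF13639", "RING", "10", "60",
            "1e-12", "T", "2026-01-01"), collapse = "\t"),
    paste(c("AT1G01010.1", "md5", "300", "PANTHER", "PTHR1", "x", "5", "80",
            "1e-5", "T", "2026-01-01"), collapse = "\t"),
    paste(c("AT1G02020.1", "md5", "200", "SMART", "SM00184", "RING", "90", "40",
            "1e-8", "T", "2026-01-01"), collapse = "\t"),
    "short\tline"
  ), tsv)
  suppressMessages(ann <- parse_domain_table(tsv))
  expect_equal(nrow(ann), 2)             # inverted span + short line dropped
  expect_equal(ann$known_db, c(TRUE, FALSE))
  expect_setequal(ring_signature_dbs(),
                  c("Gene3D", "SUPERFAMILY", "ProSiteProfiles", "SMART",
                    "Pfam", "ProSitePatterns"))
})

test_that("ligand location matches the brute-force enumeration oracle", {
  # planted motifs: positions recovered exactly
  pr <- plant_ring_proteome(n_proteins = 25, seed = 6)
  for (id in names(pr$truth$planted)) {
    loc <- locate_ring_ligands(pr$proteins[[id]])
    expect_equal(as.integer(loc$positions),
                 as.integer(pr$truth$planted[[id]]$positions))
  }
  # all-alanine and motif-free background proteins: no match
  expect_null(locate_ring_ligands(strrep("A", 150)))
  bg <- names(pr$proteins)[is.na(pr$truth$classes)]
  for (id in bg) expect_null(locate_ring_ligands(pr$proteins[[id]]))

  # random metal-rich sequences, incl. multi-match cases: oracle agreement
  n_matched <- 0
  for (seed in 1:120) {
    s <- random_ringish_seq(seed, len = 60 + (seed %% 120))
    loc <- locate_ring_ligands(s)
    ora <- ring_oracle(s)
    if (is.null(ora)) {
      expect_null(loc)
    } else {
      n_matched <- n_matched + 1
      expect_equal(as.integer(loc$positions), ora,
                   info = paste("seed", seed))
    }
  }
  expect_gt(n_matched, 10)  # the suite must actually exercise matches
})

test_that("leftmost-longest selection wins over later or shorter matches", {
  gb <- ring_spacing()$gap_bounds
  mk <- function(gaps, res = rep("C", 8)) {
    out <- character(0)
    for (i in 1:8) {
      out <- c(out, res[i], if (i < 8) rep("A", gaps[i]) else character(0))
    }
    paste(out, collapse = "")
  }
  core <- mk(c(2, 9, 1, 2, 2, 4, 2))
  # two sequential motifs: the leftmost is reported
  s2 <- paste0("AAA", core, "GGG", mk(c(2, 12, 2, 3, 2, 6, 2)))
  loc <- locate_ring_ligands(s2)
  expect_equal(loc$positions[1], 4L)
  expect_equal(as.integer(loc$positions), ring_oracle(s2))
  # span restriction: the second motif is found when the span excludes the first
  off <- 3 + nchar(core) + 3
  loc2 <- locate_ring_ligands(s2, span = c(off + 1, nchar(s2)))
  expect_equal(loc2$positions[1], off + 1L)
})

test_that("subtype classification matches the hand-coded rule oracle on all pairs", {
  # enumerate every (pos4, pos5) residue pair over the ligand alphabet + other
  alphabet <- c("C", "H", "D", "S", "T", "A")
  for (r4 in alphabet) {
    for (r5 in alphabet) {
      res <- c("C", "C", "C", r4, r5, "C", "C", "C")
      expect_equal(classify_ring(res), ring_class_oracle(res),
                   info = paste(r4, r5))
    }
  }
  # classification is total over random residue tuples
  classes <- c("HC", "H2", "v", "C2", "D", "S/T", "G", "non-canonical")
  set.seed(42)
  for (i in 1:200) {
    res <- sample(c(alphabet, "G", "W"), 8, TRUE)
    expect_true(classify_ring(res) %in% classes)
  }
  expect_error(classify_ring(c("C", "C")), "8 residues")
})

test_that("proteome screen recovers planted classes and tiers signature-only proteins", {
  pr <- plant_ring_proteome(n_proteins = 20, seed = 12)
  res <- find_ring_domains(pr$proteins, pr$annotations)
  expect_equal(sort(res$hits$protein_id), sort(names(pr$truth$planted)))
  for (i in seq_len(nrow(res$hits))) {
    id <- res$hits$protein_id[i]
    expect_equal(res$hits$ring_class[i], pr$truth$planted[[id]]$class)
  }
  # break one motif: protein drops to the signature-only tier
  broken <- pr$proteins
  id1 <- res$hits$protein_id[1]
  pos <- pr$truth$planted[[id1]]$positions
  substr(broken[[id1]], pos[1], pos[1]) <- "A"
  res2 <- find_ring_domains(broken, pr$annotations)
  expect_true(id1 %in% res2$signature_only)
  expect_false(id1 %in% res2$hits$protein_id)
})

test_that("release reconciliation partitions old ids with reason codes", {
  expect_equal(collapse_isoforms(c("AT1G01010.1", "AT1G01010.2", "AT2G0001")),
               c("AT1G01010", "AT2G0001"))
  new <- sprintf("AT1G%05d", 1:10)
  r <- reconcile(new, new)
  expect_equal(length(r$matched), 10)
  expect_equal(nrow(r$dropped), 0)
  expect_equal(length(r$newly_identified), 0)

  # partition mirroring the published curation: 6 merged, 10 no-RING,
  # 3 absent, 3 pseudogene, 7 split, 2 transposable -> 31 dropped
  reasons <- rep(c("merged", "no-RING-domain", "absent-from-db", "pseudogene",
                   "split-new-locus", "transposable-element"),
                 times = c(6, 10, 3, 3, 7, 2))
  gone <- sprintf("OLD%02d", seq_along(reasons))
  old <- c(new[1:5], gone)
  ev <- data.frame(id = gone, reason = reasons)
  rep <- reconcile(new, old, ev)
  expect_equal(unname(rep$counts["dropped"]), 31)
  expect_equal(unname(rep$counts["merged"]), 6)
  expect_equal(unname(rep$counts["no-RING-domain"]), 10)
  expect_equal(unname(rep$counts["split-new-locus"]), 7)
  expect_equal(length(rep$matched) + nrow(rep$dropped), length(old))
  expect_equal(length(rep$newly_identified), 5)

  # unmatched id without evidence is reported unresolved, unknown codes error
  r2 <- reconcile(new, c(new[1], "GHOST"))
  expect_equal(r2$dropped$reason, "unresolved")
  expect_error(reconcile(new, c(new[1], "X1"),
                         data.frame(id = "X1", reason = "vanished")),
               "unknown reason")
})
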