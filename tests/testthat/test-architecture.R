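test_that("junction spacing follows the downstream.start - upstream.end - 1 rule", {
  rec <- mitogenome_record("j", rbind(
    gene_feature("a", "tRNA", "N", 3415, 3481),
    gene_feature("b", "tRNA", "N", 3481, 3547)), length = 4000)
  j <- junction_analysis(rec, closure = FALSE)
  expect_equal(j$spacing, -1L)  # one shared base counts as overlap 1

  rec2 <- mitogenome_record("j2", rbind(
    gene_feature("r", "rRNA", "J", 8109, 8793),
    gene_feature("i", "tRNA", "N", 9128, 9192)), length = 10000)
  expect_equal(junction_analysis(rec2, closure = FALSE)$spacing, 334L)

  rec3 <- mitogenome_record("j3", rbind(
    gene_feature("x", "PCG", "N", 1, 10), gene_feature("y", "PCG", "N", 11, 20)),
    length = 30)
  j3 <- junction_analysis(rec3)
  expect_equal(j3$spacing, c(0L, 10L))  # abutting + circular closure
  expect_true(j3$is_circular_closure[2])

  expect_error(junction_analysis(
    mitogenome_record("one", rbind(gene_feature("a", "tRNA", "N", 1, 5)),
                      length = 10)), "at least 2")
})

test_that("architecture summary reproduces published bookkeeping from the printed column", {
  fx <- make_paper_fixture()
  s1 <- summarize_architecture(junctions_from_printed(fx$nepalensis),
                               fx$nepalensis$features,
                               genome_length = fx$nepalensis$length)
  expect_equal(s1$n_overlaps, 15L)
  expect_equal(s1$overlap_total_bp, 116L)
  expect_equal(s1$overlap_range, c(1L, 41L))
  expect_equal(s1$gap_total_bp, 464L)
  expect_equal(s1$gap_range, c(2L, 334L))

  s2 <- summarize_architecture(junctions_from_printed(fx$yeni),
                               fx$yeni$features,
                               genome_length = fx$yeni$length)
  expect_equal(s2$n_overlaps, 14L)
  expect_equal(s2$overlap_total_bp, 49L)
  expect_equal(s2$overlap_range, c(1L, 13L))

  toy <- data.frame(upstream = "a", downstream = "b", spacing = -5L,
                    is_circular_closure = FALSE)
  st <- summarize_architecture(toy, fx$nepalensis$features[0, ])
  expect_equal(st$n_overlaps, 1L)
  expect_equal(st$overlap_total_bp, 5L)
  expect_equal(st$overlap_range, c(5L, 5L))
  expect_warning(summarize_architecture(toy[0, ], fx$nepalensis$features[0, ]),
                 "empty")
})

test_that("internal junctions recomputed from coordinates match every printed value", {
  fx <- make_paper_fixture()
  for (sp in names(fx)) {
    jc <- junction_analysis(fx[[sp]])
    jp <- junctions_from_printed(fx[[sp]])
    internal <- !jc$is_circular_closure
    expect_equal(jc$spacing[internal], jp$spacing[internal])
  }
  # the circular closure is the one place the printed table and the
  # coordinates disagree (off by one)
  jc1 <- junction_analysis(fx$nepalensis)
  expect_equal(jc1$spacing[jc1$is_circular_closure], 8L)
  jp1 <- junctions_from_printed(fx$nepalensis)
  expect_equal(jp1$spacing[jp1$is_circular_closure], 7L)
})

test_that("strand census and class totals match the published organization", {
  fx <- make_paper_fixture()
  cen <- strand_census(fx$nepalensis$features)
  expect_equal(cen[["J"]], 14L)
  expect_equal(sum(cen), nrow(fx$nepalensis$features))
  expect_equal(strand_census(fx$yeni$features)[["J"]], 14L)

  ct <- class_totals(fx$nepalensis$features, fx$nepalensis$length)
  expect_equal(ct[["PCG"]], 10828)
  expect_equal(ct[["tRNA"]], 1370)
  expect_equal(ct[["control_region"]], 245)
  trna <- feature_lengths(fx$nepalensis$features)[
    fx$nepalensis$features$feature_class == "tRNA"]
  expect_equal(range(trna), c(55L, 67L))

  expect_equal(class_totals(fx$yeni$features)[["control_region"]], 0)
  expect_error(strand_census(fx$nepalensis$features[0, ]), "empty")
  bad <- fx$nepalensis$features; bad$strand[1] <- "X"
  expect_error(strand_census(bad), "unknown strand")

  set.seed(1)
  for (i in 1:3) {
    n <- sample(5:30, 1)
    f <- do.call(rbind, lapply(seq_len(n), function(k)
      gene_feature(paste0("g", k), "tRNA", sample(c("J", "N"), 1),
                   k * 100, k * 100 + 59)))
    expect_equal(sum(strand_census(f)), n)
  }
})

test_that("anticodon check scans the central third and agrees with a substring oracle", {
  len <- 63
  set.seed(4)
  s <- gsub("GCA", "GTA", mitocomp:::random_dna(len, 0.5))  # clear GCA out
  mid <- floor((len - 3) / 2) + 1
  substr(s, mid, mid + 2) <- "GCA"
  rec <- mitogenome_record("t", rbind(
    gene_feature("trnC", "tRNA", "N", 1, len, anticodon = "GCA")),
    sequence = s)
  chk <- anticodon_check(rec, "trnC")
  expect_true(chk$found)
  # brute-force search restricted to the window
  lo <- max(1, floor(len / 3)); hi <- min(len, ceiling(2 * len / 3))
  hits <- which(vapply(lo:(hi - 2), function(p)
    substr(s, p, p + 2) == "GCA", logical(1)))
  expect_equal(chk$position, lo + hits[1] - 1)

  s2 <- gsub("GCA", "GTA", mitocomp:::random_dna(len, 0.5))
  rec2 <- mitogenome_record("t2", rbind(
    gene_feature("trnC", "tRNA", "N", 1, len, anticodon = "GCA")),
    sequence = s2)
  expect_false(anticodon_check(rec2, "trnC")$found)

  rec3 <- toy_record()
  expect_error(anticodon_check(rec3, "g1"), "tRNA")
})

test_that("circular bookkeeping identity holds on simulated genomes", {
  for (s in c(2, 13)) {
    rec <- simulate_mitogenome(simulation_spec(seed = s))
    j <- junction_analysis(rec)
    lens <- feature_lengths(rec$features, rec$length)
    # sum of lengths - overlaps + gaps closes the circle
    expect_equal(sum(lens) + sum(j$spacing), rec$length)
  }
})
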