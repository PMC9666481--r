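test_that("incomplete stops are completed by the polyadenylation convention", {
  # 676-nt CDS ending in T -> completed to 678 with flag T(AA)
  set.seed(5)
  body <- paste(mitocomp:::draw_codon(224, 0.6), collapse = "")
  cds676 <- paste0("ATG", body, "T")
  rec <- mitogenome_record("r", rbind(
    gene_feature("cox2", "PCG", "N", 1, 676)), sequence = cds676)
  got <- extract_cds(rec, "cox2")
  expect_equal(nchar(got$cds), 678L)
  expect_equal(got$completion, "T(AA)")
  expect_match(got$cds, "TAA$")

  # complete CDS passes through unchanged
  rec2 <- mitogenome_record("r2", rbind(
    gene_feature("g", "PCG", "N", 1, 9)), sequence = "ATGAAATAA")
  got2 <- extract_cds(rec2, "g")
  expect_equal(got2, list(cds = "ATGAAATAA", completion = "none"))

  # 677-nt CDS ending TA -> completed to 678 with flag TA(A)
  cds677 <- paste0("ATG", body, "TA")
  rec3 <- mitogenome_record("r3", rbind(
    gene_feature("nad1", "PCG", "N", 1, 677)), sequence = cds677)
  got3 <- extract_cds(rec3, "nad1")
  expect_equal(nchar(got3$cds), 678L)
  expect_equal(got3$completion, "TA(A)")

  # a dangling base that is not T is refused
  rec4 <- mitogenome_record("r4", rbind(
    gene_feature("g", "PCG", "N", 1, 10)), sequence = "ATGAAATAAG")
  expect_error(extract_cds(rec4, "g"), "not an incomplete stop")
  expect_error(extract_cds(toy_record(), "t1"), "PCG")
})

test_that("translation under the invertebrate mitochondrial code matches an independent oracle", {
  expect_equal(translate_cds("ATGTTTTAA"), "MF")
  # table 5 specifics: ATA=Met, TGA=Trp, AGA=Ser
  expect_equal(translate_cds("ATATGAAGA"), "MWS")
  expect_error(translate_cds(paste0("ATG", "TTT", "TAA", "AAA", "TAA")),
               "internal stop codon at codon 3")

  set.seed(6)
  cds <- paste(mitocomp:::draw_codon(300, 0.7), collapse = "")
  mine <- translate_cds(cds)
  oracle <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = Biostrings::getGeneticCode("5")))
  expect_equal(mine, oracle)
})

test_that("start/stop census reproduces the generator's drawn codons exactly", {
  rec <- simulate_mitogenome(simulation_spec(seed = 21))
  cen <- start_stop_census(rec)
  f <- rec$features[rec$features$feature_class == "PCG", ]
  expect_equal(cen$gene, f$name)
  expect_equal(cen$start_codon, f$start_codon)
  # drawn incomplete stops surface in the printed notation
  expect_equal(cen$stop_codon,
               ifelse(f$stop_codon == "T", "T(AA)",
                      ifelse(f$stop_codon == "TA", "TA(A)", f$stop_codon)))
  # template assignments carry the published single-T set
  expect_equal(cen$stop_codon[cen$gene %in% c("cox2", "cox3", "nad4", "nad6")],
               rep("T(AA)", 4))
  expect_true(all(grepl("^AT[ACGT]$", cen$start_codon)))
  # a TAG terminator is classified as canonical, not incomplete
  expect_equal(cen$stop_codon[cen$gene == "cytb"], "TAG")

  # a non-ATN start is recorded verbatim with a warning
  rec2 <- mitogenome_record("w", rbind(
    gene_feature("odd", "PCG", "N", 1, 9)), sequence = "GTGAAATAA")
  expect_warning(cen2 <- start_stop_census(rec2), "non-ATN")
  expect_equal(cen2$start_codon, "GTG")
})

test_that("RSCU has the defining uniform, single-codon and hand-tallied behaviours", {
  # equal use of a full family -> RSCU 1 for every member
  leu6 <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  tab <- rscu(paste(leu6, collapse = ""))
  expect_equal(tab$codons$rscu[tab$codons$aa == "L"], rep(1, 6))

  # single codon used -> RSCU = family size, siblings 0
  tab2 <- rscu("TTATTATTA")
  leu <- tab2$codons[tab2$codons$aa == "L", ]
  expect_equal(leu$rscu[leu$codon == "TTA"], 6)
  expect_equal(sum(leu$rscu), 6)  # family sum = family size
  expect_equal(tab2$codons$rscu[tab2$codons$aa == "K"], rep(0, 2))

  # hand-tallied toy: 3 GGA + 1 GGG (Gly, family of 4): RSCU 3*4/4=3, 1*4/4=1
  tab3 <- rscu("GGAGGAGGAGGG")
  gly <- tab3$codons[tab3$codons$aa == "G", ]
  expect_equal(gly$rscu[gly$codon == "GGA"], 3)
  expect_equal(gly$rscu[gly$codon == "GGG"], 1)
  expect_equal(gly$rscu[gly$codon == "GGC"], 0)
  expect_equal(tab3$total_aa, 4L)

  # stop codons excluded from counts and totals
  tab4 <- rscu("ATGTAA")
  expect_equal(tab4$total_aa, 1L)
  expect_false("*" %in% tab4$codons$aa)
})

test_that("RSCU family means equal 1 and totals are consistent on simulated PCGs", {
  rec <- simulate_mitogenome(simulation_spec(seed = 4))
  cds <- vapply(which(rec$features$feature_class == "PCG"),
                function(i) extract_cds(rec, i)$cds, character(1))
  tab <- rscu(cds)
  fam_means <- tapply(tab$codons$rscu, tab$codons$aa, mean)
  used <- names(which(tapply(tab$codons$count, tab$codons$aa, sum) > 0))
  expect_equal(as.numeric(fam_means[used]), rep(1, length(used)),
               tolerance = 1e-12)
  expect_equal(sum(tab$codons$count), tab$total_aa)
  expect_equal(sum(tab$aa_freq), 100)
  # no internal stops anywhere in generator output
  expect_no_error(lapply(cds, translate_cds))
})

test_that("amino-acid ranking behaves and AT-rich genomes favour Phe/Leu/Ile/Met", {
  toy <- rscu(paste(c(rep("TTA", 10), rep("TTT", 5)), collapse = ""))
  rk <- aa_frequencies(toy)
  expect_equal(rk$aa[1:2], c("L", "F"))
  expect_equal(rk$pct[1:2], c(200 / 3, 100 / 3))
  expect_equal(sum(rk$pct), 100)

  rec <- simulate_mitogenome(simulation_spec(seed = 16))
  cds <- vapply(which(rec$features$feature_class == "PCG"),
                function(i) extract_cds(rec, i)$cds, character(1))
  rk2 <- aa_frequencies(rscu(cds))
  # AT-rich codon families (Phe/Leu/Ile) sit in the top ranks at ~78% A+T,
  # GC-rich families (Arg/Ala/Gly/Pro) at the bottom
  expect_true(all(c("F", "L", "I") %in% rk2$aa[1:8]))
  expect_true(all(match(c("R", "A", "G", "P"), rk2$aa) > 8))
  expect_error(aa_frequencies(structure(list(total_aa = 0),
                                        class = "codon_usage_table")),
               "empty")
})
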