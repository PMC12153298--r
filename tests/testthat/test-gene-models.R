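# A hand-built locus used by several boundary tests: the CDS has no internal
# ATG or TAA in its first/last 6 codons, so trimmed homology boundaries must
# snap back exactly to the planted start/stop.
safe_cds <- function() {
  paste0("ATG", strrep("GAC", 6), "TGGGAATCT", strrep("CTC", 6), "TAA")
}

test_that("HSPs merge to min/max coordinates per strand-frame group", {
  genome <- tibble::tibble(scaffold = "s1", seq = strrep("A", 600))
  h <- dplyr::bind_rows(
    hsp_row("q1", "s1", 100L, 200L, "+", qstart = 1L, qend = 33L, qlen = 140L),
    hsp_row("q1", "s1", 400L, 520L, "+", qstart = 101L, qend = 140L, qlen = 140L)
  )
  r <- merge_hsps(h, genome)
  expect_equal(nrow(r), 1)
  expect_equal(r$min_coord, 100L)
  expect_equal(r$max_coord, 520L)
  expect_equal(r$n_hsps, 2L)

  # opposite-strand HSP for the same pair: only the best HSP's group remains
  h2 <- dplyr::bind_rows(
    hsp_row("q1", "s1", 100L, 200L, "+", bitscore = 900),
    hsp_row("q1", "s1", 300L, 360L, "-", bitscore = 50)
  )
  r2 <- merge_hsps(h2, genome)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$strand, "+")
  expect_equal(r2$max_coord, 200L)

  one <- merge_hsps(hsp_row("q9", "s1", 12L, 90L), genome)
  expect_equal(c(one$min_coord, one$max_coord), c(12L, 90L))

  # above-threshold e-values and empty input are dropped silently
  expect_equal(nrow(merge_hsps(hsp_row("qx", "s1", 0L, 30L, evalue = 1e-3),
                               genome)), 0)
  expect_equal(nrow(merge_hsps(h[0, ], genome)), 0)
})

test_that("boundary extension recovers planted starts and stops", {
  cds <- safe_cds()
  loc <- planted_locus(strrep("C", 60), cds, strrep("G", 60))
  # homology trimmed 5 codons at each end
  rng <- tibble::tibble(qseqid = "g", scaffold = "chr1", strand = "+",
                        frame = (loc$start + 15L) %% 3L,
                        min_coord = loc$start + 15L,
                        max_coord = loc$end - 18L,  # 5 codons + stop
                        n_hsps = 1L, qstart_min = 6L, qend_max = 16L,
                        qlen = 21L)
  m <- extend_to_boundaries(rng, loc$genome, blasto)
  expect_equal(m$start, loc$start)
  expect_equal(m$end, loc$end)
  expect_true(m$complete5 && m$complete3)

  # a range already delimited by ATG..TAA is a fixed point
  rng2 <- rng |> dplyr::mutate(min_coord = loc$start, max_coord = loc$end - 3L)
  m2 <- extend_to_boundaries(rng2, loc$genome, blasto)
  expect_equal(c(m2$start, m2$end), c(loc$start, loc$end))

  # same planted gene on the minus strand
  locm <- planted_locus(strrep("C", 60), cds, strrep("G", 60), strand = "-")
  rngm <- tibble::tibble(qseqid = "g", scaffold = "chr1", strand = "-",
                         frame = (nchar(locm$genome$seq) - (locm$end - 18L)) %% 3L,
                         min_coord = locm$start + 18L,
                         max_coord = locm$end - 15L,
                         n_hsps = 1L, qstart_min = 6L, qend_max = 16L,
                         qlen = 21L)
  mm <- extend_to_boundaries(rngm, locm$genome, blasto)
  expect_equal(c(mm$start, mm$end), c(locm$start, locm$end))
  expect_equal(mm$strand, "-")
})

test_that("a scaffold ending mid-gene yields an incomplete-3' model", {
  cds_no_stop <- paste0("ATG", strrep("GAC", 10))  # runs off the scaffold
  genome <- tibble::tibble(scaffold = "s",
                           seq = paste0(strrep("C", 30), cds_no_stop))
  rng <- tibble::tibble(qseqid = "g", scaffold = "s", strand = "+",
                        frame = 0L, min_coord = 30L, max_coord = 63L,
                        n_hsps = 1L, qstart_min = 1L, qend_max = 11L,
                        qlen = 11L)
  m <- extend_to_boundaries(rng, genome, blasto)
  expect_false(m$complete3)
})

test_that("the SL rule relocates starts past upstream decoy ATGs", {
  cds <- safe_cds()
  # decoy in-frame ATG in the UTR, then the SL site, then clean leader
  utr5 <- paste0(strrep("C", 30), "ATG", strrep("C", 27))  # decoy at 30..33
  loc <- planted_locus(utr5, cds, strrep("G", 60))
  rng <- tibble::tibble(qseqid = "g", scaffold = "chr1", strand = "+",
                        frame = (loc$start + 15L) %% 3L,
                        min_coord = loc$start + 15L, max_coord = loc$end - 18L,
                        n_hsps = 1L, qstart_min = 6L, qend_max = 16L, qlen = 21L)
  m0 <- extend_to_boundaries(rng, loc$genome, blasto)
  # without SL information the decoy-free nearest upstream ATG is the truth,
  # but an SL site between decoy and truth must still pick the truth and set
  # the support flag
  sl <- tibble::tibble(scaffold = "chr1", pos = loc$start - 20L, strand = "+")
  m1 <- apply_sl_start_rule(m0, sl, loc$genome, blasto)
  expect_equal(m1$start, loc$start)
  expect_true(m1$sl_supported)

  # with no SL site the model is untouched
  m2 <- apply_sl_start_rule(m0, sl[0, ], loc$genome, blasto)
  expect_equal(m2, m0)

  # an SL site downstream of the stop is ignored with a warning
  sl_bad <- tibble::tibble(scaffold = "chr1", pos = loc$end + 10L, strand = "+")
  expect_warning(m3 <- apply_sl_start_rule(m0, sl_bad, loc$genome, blasto),
                 "ignored")
  expect_equal(m3$start, m0$start)
  expect_false(m3$sl_supported)
})

test_that("every SL-planted synthetic gene ends up SL-supported", {
  spec <- genome_sim_spec(n_genes = 80, mean_cds_len = 150, sl_fraction = 1,
                          seed = 13)
  sim <- simulate_genome(spec)
  hsps <- simulate_hsp_table(sim, frag_rate = 0.2, trim_max = 8, seed = 14)
  models <- annotate_genome(sim$genome, hsps, blasto, sl_sites = sim$sl_sites)
  expect_true(all(models$sl_supported))
})

test_that("overlap reduction keeps the longest model and tolerates 10 nt", {
  mk <- function(id, start, end, scaffold = "s") {
    tibble::tibble(id = id, scaffold = scaffold, strand = "+",
                   start = as.integer(start), end = as.integer(end),
                   complete5 = TRUE, complete3 = TRUE, sl_supported = FALSE,
                   protein_aa = as.integer((end - start) / 3 - 1),
                   hom_start = as.integer(start), hom_end = as.integer(end),
                   orf_limit = 0L)
  }
  big_overlap <- dplyr::bind_rows(mk("a", 0, 900), mk("b", 850, 1450))
  r <- reduce_overlaps(big_overlap)
  expect_equal(r$id, "a")
  expect_equal(exclusions(r)$id, "b")

  small_overlap <- dplyr::bind_rows(mk("a", 0, 900), mk("b", 892, 1500))
  r2 <- reduce_overlaps(small_overlap)
  expect_setequal(r2$id, c("a", "b"))

  tie <- dplyr::bind_rows(mk("right", 300, 600), mk("left", 250, 550))
  r3 <- reduce_overlaps(tie)
  expect_equal(r3$id, "left")   # equal lengths: leftmost wins

  # idempotence on the surviving models
  strip <- function(x) { attr(x, "exclusions") <- NULL; as.data.frame(x) }
  r4 <- reduce_overlaps(r3)
  expect_equal(strip(r4), strip(r3))
  expect_equal(nrow(exclusions(r4)), 0)
})

test_that("the 30-aa filter removes short proteins at the boundary", {
  mk <- function(id, aa) {
    tibble::tibble(id = id, scaffold = "s", strand = "+", start = 0L,
                   end = as.integer(3 * (aa + 1)), complete5 = TRUE,
                   complete3 = TRUE, sl_supported = FALSE,
                   protein_aa = as.integer(aa), hom_start = 0L,
                   hom_end = 0L, orf_limit = 0L)
  }
  models <- dplyr::bind_rows(mk("short", 29), mk("kept", 30))
  f <- filter_models(models)
  expect_equal(f$id, "kept")
  expect_equal(exclusions(f)$id, "short")
  expect_equal(nrow(filter_models(models[0, ])), 0)
})

test_that("rescue requires both coverage and a qualifying hit", {
  cds <- safe_cds()
  loc <- planted_locus(strrep("C", 30), cds, strrep("G", 30))
  cover <- function(depth) {
    tibble::tibble(scaffold = "chr1", start = loc$start, end = loc$end,
                   depth = depth)
  }
  hit <- tibble::tibble(scaffold = "chr1", start = loc$start, end = loc$end,
                        strand = "+", frame = loc$start %% 3L, evalue = 1e-9)
  none <- rescue_expressed_regions(cover(9), hit, loc$genome, blasto)
  expect_equal(nrow(none), 0)
  no_hit <- rescue_expressed_regions(cover(30), hit |> dplyr::mutate(evalue = 1e-3),
                                     loc$genome, blasto)
  expect_equal(nrow(no_hit), 0)
  got <- rescue_expressed_regions(cover(30), hit, loc$genome, blasto)
  expect_equal(nrow(got), 1)
  # rescued regions are raw expressed spans, not models: the final TAA is
  # still read as Glu here
  expect_equal(got$protein, translate_cds(cds, blasto, complete3 = FALSE))
})

test_that("models recover planted genes under fragmentation and trimming", {
  spec <- genome_sim_spec(n_genes = 250, mean_cds_len = 200, seed = 31)
  sim <- simulate_genome(spec)
  hsps <- simulate_hsp_table(sim, frag_rate = 0.3, trim_max = 10, seed = 32)
  models <- annotate_genome(sim$genome, hsps, blasto, sl_sites = sim$sl_sites)
  m <- models[match(sim$genes$id, models$id), ]
  exact <- m$start == sim$genes$start & m$end == sim$genes$end
  expect_gte(mean(exact, na.rm = TRUE), 0.95)
  # every complete model terminates in TAA
  cds <- models_to_cds(models, sim$genome, blasto)
  term <- substring(cds$seq, nchar(cds$seq) - 2)
  expect_true(all(term[cds$complete3] == "TAA"))
})
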