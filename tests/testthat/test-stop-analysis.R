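test_that("the genuine stop is the codon right after a complete-3' alignment", {
  cds <- paste0("ATG", strrep("GAC", 8), "TAA")
  loc <- planted_locus(strrep("C", 30), cds, strrep("G", 30))
  h <- hsp_row("q", "chr1", loc$start, loc$end - 3L)  # full protein aligned
  got <- find_genuine_stop(h, loc$genome)
  expect_equal(got$triplet, "TAA")

  # minus strand: the triplet is read on the reverse complement
  locm <- planted_locus(strrep("C", 30), cds, strrep("G", 30), strand = "-")
  hm <- hsp_row("q", "chr1", locm$start + 3L, locm$end, strand = "-")
  expect_equal(find_genuine_stop(hm, locm$genome)$triplet, "TAA")

  # incomplete 3' query coverage is excluded
  h_inc <- h |> dplyr::mutate(qend = qlen - 1L)
  expect_equal(nrow(find_genuine_stop(h_inc, loc$genome)), 0)

  # alignment ending at the scaffold edge gets no call
  edge_genome <- tibble::tibble(scaffold = "chr1",
                                seq = substr(loc$genome$seq, 1, loc$end - 3L + 2L))
  expect_true(find_genuine_stop(h, edge_genome)$no_call)
})

test_that("genuine stops agree with truth on untrimmed synthetic HSPs", {
  spec <- genome_sim_spec(n_genes = 120, mean_cds_len = 150, seed = 17)
  sim <- simulate_genome(spec)
  hsps <- simulate_hsp_table(sim, frag_rate = 0, trim_max = 0, decoy_rate = 0,
                             seed = 18)
  got <- find_genuine_stop(hsps, sim$genome)
  expect_equal(nrow(got), nrow(sim$genes))
  expect_false(any(got$no_call))
  expect_true(all(got$triplet == sim$genes$stop_codon[match(got$qseqid, sim$genes$id)]))
})

test_that("stop usage recovers planted terminator probabilities", {
  all_taa <- cds_from_seqs(replicate(5, random_cds_seq(20)), code = blasto)
  u <- stop_usage_table(all_taa)
  expect_equal(u$n, c(5L, 0L, 0L))

  # canonical-code set with planted terminator mix; UAG most frequent
  spec <- genome_sim_spec(n_genes = 600, mean_cds_len = 60, seed = 23,
                          code = canon,
                          codon_freqs = default_codon_freqs(canon),
                          stop_probs = c(TAA = 0.2, TAG = 0.5, TGA = 0.3),
                          sl_fraction = 0)
  sim <- simulate_genome(spec)
  u2 <- stop_usage_table(sim_truth_cds(sim))
  expect_equal(sum(u2$n), 600L)
  for (i in 1:3) {
    p <- c(0.2, 0.5, 0.3)[i]
    expect_lt(abs(u2$fraction[i] - p), 3 * sqrt(p * (1 - p) / 600))
  }
  expect_equal(u2$triplet[which.max(u2$n)], "TAG")

  # records lacking a complete 3' end are excluded
  mixed <- cds_from_seqs(replicate(4, random_cds_seq(20)))
  mixed$complete3[1] <- FALSE
  expect_equal(sum(stop_usage_table(cds_set(mixed, blasto))$n), 3L)
})

test_that("downstream profile counts stop triplets per frame and position", {
  fl <- tibble::tibble(id = "g", seq = paste0("TAATAATAA", strrep("C", 70)))
  prof <- downstream_stop_profile(fl, blasto)
  f1 <- prof |> dplyr::filter(frame == 1)
  expect_equal(f1$count[1:4], c(1L, 1L, 1L, 0L))
  expect_equal(sum(prof$count[prof$frame != 1]), 0)

  # frame partition: the three frame tracks tile the flank without overlap
  w <- 75
  avail <- prof |> dplyr::group_by(frame) |> dplyr::summarise(n = sum(denominator))
  expect_true(all(avail$n <= w %/% 3 * 1))
})

test_that("planted frame-1 UAA enrichment decays at K and spares frames 2-3", {
  spec <- genome_sim_spec(n_genes = 1200, mean_cds_len = 60, seed = 29,
                          utr3_uaa_fold = 3, utr3_uaa_decay = 14,
                          utr3_zigzag_amp = 0)
  sim <- simulate_genome(spec)
  prof <- downstream_stop_profile(
    tibble::tibble(id = sim$genes$id, seq = sim$genes$utr3), blasto)
  p_bg <- 0.375^3
  rate <- function(fr, pos) {
    d <- prof[prof$frame == fr & prof$position %in% pos, ]
    sum(d$count) / sum(d$denominator)
  }
  sd_cell <- sqrt(p_bg * (1 - p_bg) / 1200)
  # enriched early frame-1 positions sit well above background...
  expect_gt(rate(1, 1:14), p_bg + 3 * sd_cell)
  # ...the post-decay tail and the other frames do not
  expect_lt(abs(rate(1, 16:25) - p_bg), 3 * sd_cell)
  for (fr in 2:3) expect_lt(abs(rate(fr, 1:25) - p_bg), 3 * sd_cell)
})

test_that("upstream profile sees terminal-Glu UAG at -1 and short CDSs", {
  s <- paste0("ATG", strrep("GAC", 5), "GAGTAGTAA")
  up <- upstream_stop_profile(one_cds(s), blasto, n_codons = 5)
  at <- function(pos, tr) up$count[up$position == pos & up$triplet == tr]
  expect_equal(at(-1L, "TAG"), 1L)
  expect_equal(at(-2L, "TAG"), 0L)

  ten <- one_cds(paste0("ATG", strrep("GAC", 9), "TAA"), id = "ten")
  up10 <- upstream_stop_profile(ten, blasto, n_codons = 25)
  expect_true(all(up10$denominator[up10$position < -10] == 0))
  expect_true(all(up10$denominator[up10$position >= -10] == 1))
})

test_that("the filtered 3'UTR set tracks membership and downstream GC", {
  fl <- tibble::tibble(
    id = c("starts_taa", "all_gc"),
    seq = c(paste0("TAA", strrep("C", 117)), strrep("GC", 60))
  )
  fs <- filtered_3utr_set(fl, blasto)
  expect_equal(fs$member, c(TRUE, FALSE))
  expect_equal(fs$gc_downstream[2], 1.0)
  expect_false(any(fs$short_flank))

  # planted membership probability from the generator's own parameters
  spec <- genome_sim_spec(n_genes = 1000, mean_cds_len = 60, seed = 37,
                          utr3_zigzag_amp = 0)
  sim <- simulate_genome(spec)
  fs2 <- filtered_3utr_set(tibble::tibble(id = sim$genes$id,
                                          seq = sim$genes$utr3), blasto)
  p_bg <- 0.375^3
  p_enr <- spec$utr3_uaa_fold * p_bg
  K <- spec$utr3_uaa_decay
  p_member <- 1 - (1 - p_enr)^K * (1 - p_bg)^(30 - K)
  got <- attr(fs2, "fraction")
  expect_lt(abs(got - p_member), 3 * sqrt(p_member * (1 - p_member) / 1000))
})

test_that("alternation score separates zig-zag from balanced sequence", {
  # period-2 alternating A/T is the maximal-score pattern
  zig <- tibble::tibble(id = "z", seq = strrep("AT", 30))
  sc <- zigzag_scores(zigzag_au_profile(zig))
  expect_equal(sc$score, 1)

  set.seed(41)
  iid <- tibble::tibble(id = sprintf("g%d", 1:400),
                        seq = vapply(1:400, function(i) {
                          paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                                       prob = c(.375, .125, .125, .375)),
                                collapse = "")
                        }, character(1)))
  sc_iid <- zigzag_scores(zigzag_au_profile(iid))
  expect_lt(sc_iid$score, 0.06)

  # generator: planted 3'UTR zig-zag exceeds the balanced 5' side
  spec <- genome_sim_spec(n_genes = 400, mean_cds_len = 60, seed = 43,
                          utr3_zigzag_amp = 0.2, utr3_uaa_fold = 1)
  sim <- simulate_genome(spec)
  fl3 <- tibble::tibble(id = sim$genes$id, seq = sim$genes$utr3)
  fl5 <- cut_flanks(sim$genes, sim$genome, width = 60, side = "5p")
  prof <- zigzag_au_profile(fl3, fl5)
  sc2 <- zigzag_scores(prof)
  expect_gt(sc2$score[sc2$side == "3p"], 2 * sc2$score[sc2$side == "5p"])
})
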