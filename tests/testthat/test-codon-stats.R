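test_that("ifRC statistics match hand counts", {
  # internal codons GAA GAA TAA; the final TAA terminates
  p <- ifrc_summary(one_cds("GAAGAATAATAA"))
  expect_equal(p$glu1, 1)
  expect_equal(p$ifrc_freq, 1 / 3)
  expect_equal(p$n_codons, 3L)
  expect_equal(p$pct_uaa, 100 * 1 / 3)
  expect_true(is.na(p$pct_uga))  # no TGA and no TGG: undefined, not 0

  # a set without internal reassigned codons has ifrc_freq 0
  clean <- one_cds(paste0("ATG", strrep("GAA", 5), "TAA"))
  expect_equal(ifrc_summary(clean)$ifrc_freq, 0)
})

test_that("ifRC statistics equal brute-force recomputation on random sets", {
  set.seed(7)
  for (rep in 1:10) {
    seqs <- replicate(8, random_cds_seq(sample(20:80, 1)))
    prof <- ifrc_summary(cds_from_seqs(seqs))
    agg <- ifrc_aggregate(prof)
    want <- oracle_ifrc(seqs)
    expect_equal(agg$glu1, want$glu1)
    expect_equal(agg$glu2, want$glu2)
    expect_equal(agg$trp, want$trp)
    expect_equal(agg$ifrc_freq, want$ifrc)
  }
})

test_that("fraction identities hold: families plus the rest sum to one", {
  set.seed(19)
  seqs <- replicate(10, random_cds_seq(50))
  prof <- ifrc_summary(cds_from_seqs(seqs))
  agg <- ifrc_aggregate(prof)
  counts <- aggregate_codon_counts(attr(prof, "counts"))
  other <- counts |>
    dplyr::filter(!codon %in% c("GAA", "TAA", "GAG", "TAG", "TGG", "TGA")) |>
    dplyr::summarise(f = sum(count) / agg$n_codons)
  expect_equal(agg$glu1 + agg$glu2 + agg$trp + other$f, 1)
  # aggregate equals the count-weighted mean of per-CDS values
  expect_equal(agg$glu1, sum(prof$glu1 * prof$n_codons) / sum(prof$n_codons))
})

test_that("pct_UGA is 0 without TGA and 100 without TGG", {
  no_tga <- one_cds(paste0("ATG", strrep("TGG", 4), "TAA"))
  expect_equal(ifrc_summary(no_tga)$pct_uga, 0)
  no_tgg <- one_cds(paste0("ATG", strrep("TGA", 4), "TAA"))
  expect_equal(ifrc_summary(no_tgg)$pct_uga, 100)
})

test_that("relative adaptiveness divides by the family maximum", {
  # Glu family counts {GAA: 60, TAA: 40, GAG: 0, TAG: 0}
  seqs <- c(paste0(strrep("GAA", 60), strrep("TAA", 40), "TAA"))
  w <- relative_adaptiveness(cds_from_seqs(seqs))
  get_w <- function(cod) w$w[w$codon == cod]
  expect_equal(get_w("GAA"), 1)
  expect_equal(get_w("TAA"), 2 / 3)
  expect_equal(get_w("GAG"), 0.5 / 60)  # unobserved: 0.5 / max count

  # every observed codon of a single-used-codon family has w = 1
  expect_equal(get_w("ATG"), NA_real_)  # ATG never observed here (flagged NA family)

  set.seed(3)
  seqs2 <- replicate(12, random_cds_seq(60))
  w2 <- relative_adaptiveness(cds_from_seqs(seqs2))
  # brute-force recomputation from raw counts
  cnt <- oracle_count_codons(paste(substr(seqs2, 1, nchar(seqs2) - 3), collapse = ""),
                             drop_terminal = FALSE)
  fams <- codon_families(blasto)
  for (i in sample(nrow(w2), 12)) {
    cod <- w2$codon[i]
    fam <- fams$codon[fams$aa == w2$aa[i]]
    mx <- max(cnt[fam], na.rm = TRUE)
    obs <- if (cod %in% names(cnt)) cnt[[cod]] else 0
    expect_equal(w2$w[i], if (obs > 0) obs / mx else 0.5 / mx)
  }
})

test_that("w and CAI are invariant under reference scaling", {
  # the 0.5/max-count convention for unobserved codons is deliberately not
  # scale-free, so invariance is asserted over observed codons and over
  # targets built from them
  set.seed(9)
  seqs <- replicate(6, random_cds_seq(40))
  w1 <- relative_adaptiveness(cds_from_seqs(seqs))
  w3 <- relative_adaptiveness(cds_from_seqs(rep(seqs, 3)))
  observed <- w1$count > 0
  expect_equal(w1$w[observed], w3$w[observed])
  target <- cds_from_seqs(seqs[1:3])
  expect_equal(cai_score(target, w1)$cai, cai_score(target, w3)$cai)
})

test_that("CAI reproduces its defining limits and the log-domain oracle", {
  # reference in which every used codon is its family's only one
  ref <- cds_from_seqs(paste0(strrep("GAA", 10), strrep("TGG", 10), "TAA"))
  w <- relative_adaptiveness(ref)
  only_opt <- cds_from_seqs(paste0(strrep("GAA", 8), "TAA"))
  expect_equal(cai_score(only_opt, w)$cai, 1.0)

  # two codons with w = 1 and w = 0.25 give geometric mean 0.5
  seqs <- c(paste0(strrep("GAA", 80), strrep("TAA", 20), "TAA"))
  w2 <- relative_adaptiveness(cds_from_seqs(seqs))
  expect_equal(w2$w[w2$codon == "TAA"], 0.25)
  two <- cds_from_seqs("GAATAATAA")
  expect_equal(cai_score(two, w2)$cai, 0.5)

  # random CDS against an independent log-domain recomputation
  set.seed(13)
  ref2 <- cds_from_seqs(replicate(10, random_cds_seq(60)))
  wt <- relative_adaptiveness(ref2)
  s <- random_cds_seq(50)
  got <- cai_score(one_cds(s), wt)$cai
  skip_aa <- c("M")  # single-codon family under the reassigned code
  wmap <- stats::setNames(wt$w, wt$codon)
  fam <- stats::setNames(wt$aa, wt$codon)
  cods <- vapply(seq_len(nchar(s) / 3 - 1),
                 function(i) substr(s, 3 * i - 2, 3 * i), character(1))
  cods <- cods[!fam[cods] %in% skip_aa]
  expect_equal(got, exp(mean(log(wmap[cods]))))
})

test_that("reciprocal best hits require mutual best status", {
  ab <- dplyr::bind_rows(
    tibble::tibble(qseqid = "a1", sseqid = "b1", bitscore = 100, evalue = 1e-50),
    tibble::tibble(qseqid = "a2", sseqid = "b2", bitscore = 90, evalue = 1e-40)
  )
  ba <- dplyr::bind_rows(
    tibble::tibble(qseqid = "b1", sseqid = "a1", bitscore = 100, evalue = 1e-50),
    tibble::tibble(qseqid = "b2", sseqid = "a3", bitscore = 95, evalue = 1e-45)
  )
  pairs <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$id_a, "a1")

  # synthetic truth: identity mapping recovered completely
  ids <- sprintf("x%02d", 1:20)
  fwd <- tibble::tibble(qseqid = ids, sseqid = paste0("y", ids),
                        bitscore = 500, evalue = 1e-80)
  rev_ <- tibble::tibble(qseqid = paste0("y", ids), sseqid = ids,
                         bitscore = 500, evalue = 1e-80)
  expect_equal(nrow(reciprocal_best_hits(fwd, rev_)), 20)
})

test_that("the ifRC regression recovers exact lines and planted couplings", {
  prof <- tibble::tibble(id = sprintf("g%d", 1:10),
                         ifrc_freq = seq(0, 0.9, 0.1))
  vals <- tibble::tibble(id = prof$id, abundance = -2 * prof$ifrc_freq + 1)
  fit <- ifrc_correlates(prof, vals)
  expect_equal(unname(stats::coef(fit$model)[2]), -2)
  expect_equal(fit$r, -1)
  expect_equal(glance(fit)$slope, -2)

  const <- tibble::tibble(id = prof$id, abundance = rep(1, 10))
  fitc <- ifrc_correlates(prof, const)
  expect_equal(fitc$r, 0)
  expect_true(fitc$r_undefined)

  expect_error(ifrc_correlates(prof[1:2, ], vals[1:2, ]), "at least 3")

  # generator coupling: planted slope > 0 gives a negative fitted slope
  sim <- simulate_genome(genome_sim_spec(n_genes = 150, mean_cds_len = 120,
                                         seed = 3))
  p <- ifrc_summary(sim_truth_cds(sim))
  ab <- simulate_abundance_table(p, slope = 8, noise = 0.3, seed = 4)
  fit2 <- ifrc_correlates(p, ab)
  expect_lt(glance(fit2)$slope, 0)
  expect_lt(fit2$r, 0)
})

test_that("category comparisons flag planted shifts and respect subsampling", {
  set.seed(55)
  metric <- tibble::tibble(
    id = sprintf("g%03d", 1:120),
    value = c(rnorm(60, 0.003, 0.001), rnorm(60, 0.015, 0.004))
  )
  cats <- tibble::tibble(id = metric$id,
                         category = rep(c("cyto", "mito"), each = 60))
  cmp <- category_compare(metric, cats, n_sub = 40, seed = 5)
  expect_lt(cmp$p_adj, 0.05)
  expect_false(cmp$used_all)

  # n_sub above the category size uses all genes and flags it
  cmp2 <- category_compare(metric, cats, n_sub = 100, seed = 5)
  expect_true(cmp2$used_all)
  expect_equal(cmp2$n_a, 60L)

  tiny <- dplyr::bind_rows(cats, tibble::tibble(id = "g999", category = "solo"))
  expect_warning(
    category_compare(dplyr::bind_rows(metric, tibble::tibble(id = "g999", value = 1)),
                     tiny, seed = 5),
    "skipped")
})

test_that("identical category distributions are rarely rejected", {
  set.seed(77)
  rejections <- vapply(1:40, function(r) {
    metric <- tibble::tibble(id = sprintf("g%03d", 1:100), value = rnorm(100))
    cats <- tibble::tibble(id = metric$id,
                           category = rep(c("u", "v"), each = 50))
    any(category_compare(metric, cats, n_sub = 40, seed = r)$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})

test_that("ribosomal gene-set codon usage separates planted cyto/mito sets", {
  # cyto set depleted of ifRCs (0.3%), mito set enriched (1.5%)
  mk_set <- function(p_taa, n) {
    replicate(n, {
      body <- sample(c("TAA", "GAA", "GCT", "CTC"), 60, TRUE,
                     prob = c(p_taa, 0.3, 0.35, 0.35 - p_taa))
      paste0("ATG", paste(body, collapse = ""), "TAA")
    })
  }
  set.seed(3)
  seqs <- c(mk_set(0.003, 20), mk_set(0.05, 20))
  cds <- cds_from_seqs(seqs)
  groups <- tibble::tibble(id = cds$id,
                           group = rep(c("cyto", "mito"), each = 20))
  u <- ribosomal_codon_usage(cds, groups)
  taa <- u[u$codon == "TAA", ]
  expect_gt(taa$freq_mito, 5 * taa$freq_cyto)
  expect_true(taa$ifrc)
  expect_equal(sum(u$freq_cyto), 1)
})
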