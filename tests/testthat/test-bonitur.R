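test_that("quantitative-trait bins are upper-inclusive with ND scoring zero", {
  bins <- c(15, 30)
  expect_equal(score_quant_trait(43.8, bins), 3L)
  expect_equal(score_quant_trait(NA, bins), 0L)
  expect_equal(score_quant_trait(0, bins), 0L)
  expect_equal(score_quant_trait(15.0, bins), 1L)   # boundary is inclusive
  expect_equal(score_quant_trait(30.0, bins), 2L)
  expect_equal(score_quant_trait(30.0001, bins), 3L)
  expect_error(score_quant_trait(-1, bins), "negative")
})

test_that("inhibition bins match the published boundary convention", {
  # the published table scores a 60% inhibition as 2 points, so the
  # (30, 60] bin is closed above
  expect_equal(score_inhibition(60.0), 2L)
  expect_equal(score_inhibition(NA), 0L)
  expect_equal(score_inhibition(62.5), 3L)
  expect_equal(score_inhibition(10), 0L)
  expect_equal(score_inhibition(10.1), 1L)
  expect_equal(score_inhibition(30), 1L)
  expect_equal(score_inhibition(100), 3L)
  expect_error(score_inhibition(101), "outside")
})

test_that("rule-set construction enforces its invariants", {
  r <- bonitur_rules()
  expect_equal(r$max_total, 41L)   # 2*3 + 5*1 + 10*3
  expect_error(bonitur_rules(iaa_bins = c(30, 15)), "increasing")
  expect_error(bonitur_rules(binary_traits = c("ammonia", "made_up")),
               "unknown trait")
})

test_that("rule sets survive a YAML config round trip", {
  r <- bonitur_rules(iaa_bins = c(10, 20), binary_points = 2L)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_bonitur_rules(r, tmp)
  expect_equal(read_bonitur_rules(tmp), r)
})

test_that("campaign scoring reproduces the published elite-strain totals", {
  cards <- score_campaign(fx_traits(), fx_inhibition())
  total_of <- function(id) cards$total[cards$isolate_id == id]
  expect_equal(total_of("VCLA3"), 34L)
  expect_equal(total_of("RVRA7"), 32L)
  expect_equal(total_of("RRR46"), 21L)
  expect_equal(total_of("DNRA5"), 18L)
  expect_equal(total_of("DFLA1"), 18L)
  expect_equal(cards$rank[cards$isolate_id == "VCLA3"], 1L)
  expect_equal(cards$rank[cards$isolate_id == "RVRA7"], 2L)
  # subtotals always compose the total
  expect_equal(cards$total, cards$pgp_subtotal + cards$antifungal_subtotal)
  expect_true(all(cards$total >= 0 & cards$total <= 41))
})

test_that("an all-negative profile scores zero and a maximal one scores 41", {
  null_card <- score_isolate(profile_row(),
                             setNames(rep(NA_real_, 10), paste0("P", 1:10)))
  expect_equal(null_card$total, 0L)

  max_card <- score_isolate(
    profile_row(iaa = 50, p_solub = 250, ammonia = 5, siderophore = 60,
                n2_fixation = TRUE, acc_deaminase = TRUE, chitinase = TRUE),
    setNames(rep(95, 10), paste0("P", 1:10)))
  expect_equal(max_card$total, 41L)
})

test_that("scores are monotone and bounded under randomized profiles", {
  set.seed(42)
  rules <- bonitur_rules()
  for (i in 1:300) {
    qs <- ifelse(runif(4) < 0.3, NA, runif(4, 0, 100))
    flags <- runif(3) < 0.5
    gi <- ifelse(runif(10) < 0.5, NA, runif(10, 0, 100))
    prof <- profile_row(iaa = qs[1], p_solub = qs[2], ammonia = qs[3],
                        siderophore = min(qs[4], 100),
                        n2_fixation = flags[1], acc_deaminase = flags[2],
                        chitinase = flags[3])
    gi <- setNames(gi, paste0("P", 1:10))
    card <- score_isolate(prof, gi, rules)
    expect_gte(card$total, 0L)
    expect_lte(card$total, 41L)

    # raising any single trait value never decreases the total
    prof2 <- prof
    prof2$iaa <- if (is.na(prof$iaa)) 5 else prof$iaa * 1.5
    expect_gte(score_isolate(prof2, gi, rules)$total, card$total)

    # adding an inhibition never decreases the total
    gi2 <- gi
    j <- which(is.na(gi2))[1]
    if (!is.na(j)) {
      gi2[j] <- 50
      expect_gte(score_isolate(prof, gi2, rules)$total, card$total)
    }
  }
})

test_that("dense ranking shares ranks for ties and skips nothing", {
  cards <- data.frame(isolate_id = paste0("I", 1:7),
                      total = c(34, 32, 30, 30, 21, 18, 18))
  ranked <- rank_isolates(cards)
  expect_equal(ranked$rank, c(1, 2, 3, 3, 4, 5, 5))

  expect_equal(rank_isolates(cards[1, , drop = FALSE])$rank, 1)
  all_tied <- data.frame(isolate_id = c("A", "B"), total = c(5, 5))
  expect_equal(rank_isolates(all_tied)$rank, c(1, 1))

  # invariant under order-preserving transformation of totals
  cards2 <- cards
  cards2$total <- cards$total^2 + 1
  expect_equal(rank_isolates(cards2)$rank, ranked$rank)
  expect_error(rank_isolates(cards[0, ]), "no score cards")
})

test_that("the audit flags the published rows that disagree with recomputation", {
  cards <- score_campaign(fx_traits(), fx_inhibition())
  aud <- audit_scores(cards, fx_published())
  expect_setequal(aud$flagged_isolates, c("DNLA13", "VCRA2"))

  # VCRA2's printed points sum to 28, not its printed total of 30
  vcra2 <- aud$internal_sums[aud$internal_sums$isolate_id == "VCRA2", ]
  expect_false(vcra2$consistent)
  expect_equal(vcra2$points_sum, 28L)
  expect_equal(vcra2$printed_total, 30L)
  # every other published row is internally consistent
  expect_true(all(aud$internal_sums$consistent[
    aud$internal_sums$isolate_id != "VCRA2"]))

  # the elite strains reconcile cell-by-cell
  expect_false("VCLA3" %in% aud$cell_mismatches$isolate_id)
  expect_false("RVRA7" %in% aud$cell_mismatches$isolate_id)

  # identical tables -> empty report
  self <- audit_scores(cards, cbind(cards, row.names = NULL))
  expect_length(self$flagged_isolates, 0)
})
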