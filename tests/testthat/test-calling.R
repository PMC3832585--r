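mk_scores <- function(mean, sem = 0.2, measure = "outgrowth",
                      gene = paste0("g", seq_along(mean)), dose = 4,
                      oligo = "pool") {
  data.frame(gene = gene, oligo = oligo, dose = dose, measure = measure,
             n = 3, mean = mean, sem = sem, stringsAsFactors = FALSE)
}

test_that("hit calling thresholds the mean and grades stringency by mean - SEM", {
  calls <- call_phenotype(mk_scores(c(3.5, 3.5, 2.9, -3.2),
                                    sem = c(0.4, 0.8, 0.1, 0.1)))
  expect_equal(calls$hit, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(calls$stringency, c("stringent", "marginal", "none", "stringent"))
  expect_error(call_phenotype(mk_scores(NaN)), "non-finite")
})

test_that("direction labels map the sign convention to biology", {
  calls <- call_phenotype(rbind(
    mk_scores(c(4, -4), measure = "outgrowth", gene = c("a", "b")),
    mk_scores(c(4, -4), measure = "growth", gene = c("c", "d"))))
  # positive deviation = below the control line = shorter neurites
  expect_equal(calls$direction, c("decrease", "increase", "increase", "decrease"))
})

test_that("calls are monotone in |mean| and SEM", {
  means <- seq(2.0, 6.0, by = 0.25)
  calls <- call_phenotype(mk_scores(means, sem = 0.4))
  rank_of <- c(none = 0, marginal = 1, stringent = 2)
  expect_true(all(diff(rank_of[calls$stringency]) >= 0))
  sems <- seq(1.2, 0.05, by = -0.05)
  calls2 <- call_phenotype(mk_scores(rep(3.6, length(sems)), sem = sems))
  expect_true(all(diff(rank_of[calls2$stringency]) >= 0))
})

test_that("growth-impaired genes are excluded from the other categories", {
  sc <- rbind(mk_scores(c(-3.5, -2, 4), measure = "growth",
                        gene = c("a", "b", "c")),
              mk_scores(c(-4, -4, -4), measure = "outgrowth",
                        gene = c("a", "b", "c")))
  out <- apply_exclusions(call_phenotype(sc))
  expect_false(any(out$excluded[out$measure == "growth"]))
  expect_equal(out$excluded[out$measure == "outgrowth"],
               c(TRUE, FALSE, FALSE))  # only the -3.5 growth gene; +4 is one-sided
  expect_match(out$exclusion_reason[out$measure == "outgrowth"][1], "growth")
  # growth hit itself retained
  expect_true(out$hit[out$gene == "a" & out$measure == "growth"])
  sc_missing <- mk_scores(-4, gene = "orphan")
  expect_error(apply_exclusions(call_phenotype(sc_missing)), "orphan")
})

test_that("secondary-screen reproduction counts concordant and opposite oligos", {
  prim <- call_phenotype(mk_scores(-5, gene = "keg1"))  # increase in length
  oligos <- mk_scores(c(-4, 0.5, 1, -0.2), gene = "keg1",
                      oligo = c("A", "B", "C", "D"))
  st <- secondary_reproduction(prim, oligos)
  expect_equal(st$status, "reproduced_single")
  expect_false(st$opposite_flag)

  oligos2 <- mk_scores(c(-4, -3.5, 3.4, -0.2), gene = "keg1",
                       oligo = c("A", "B", "C", "D"))
  st2 <- secondary_reproduction(prim, oligos2)
  expect_equal(st2$status, "reproduced_multiple")
  expect_true(st2$opposite_flag)
  expect_equal(st2$n_concordant, 2)
  expect_equal(st2$n_opposite, 1)

  oligos3 <- mk_scores(c(1, -1, 2, 0), gene = "keg1",
                       oligo = c("A", "B", "C", "D"))
  expect_equal(secondary_reproduction(prim, oligos3)$status, "not_reproduced")
  expect_error(secondary_reproduction(prim, mk_scores(-4, gene = "tpx2", oligo = "A")),
               "tpx2")
})

test_that("reproduction summary reports percentages with counts", {
  st <- data.frame(status = rep(c("reproduced_multiple", "reproduced_single",
                                  "not_reproduced"), c(11, 11, 8)))
  rs <- reproduction_summary(st)
  expect_equal(rs$n_total, 30)
  expect_equal(rs$n_any, 22)
  expect_equal(rs$n_multiple, 11)
  expect_equal(rs$pct_any, 100 * 22 / 30)
  expect_equal(rs$pct_multiple, 100 * 11 / 30)
  none <- data.frame(status = rep("not_reproduced", 30))
  expect_equal(reproduction_summary(none)$pct_any, 0)
  expect_error(reproduction_summary(data.frame(status = character(0))), "non-empty")
})

test_that("class composition percentages match brute-force counting", {
  ann <- data.frame(gene = c("A", "B", "C", "D"),
                    class = c("motor", "motor", "MAP", "MAP"))
  ce <- class_enrichment(c("A", "B"), ann)
  motor <- ce[ce$class == "motor", ]
  expect_equal(motor$pct_in_hits, 100)
  expect_equal(motor$pct_in_library, 50)
  # hits = whole library => identical percentages per class
  ce2 <- class_enrichment(ann$gene, ann)
  expect_equal(ce2$pct_in_hits, ce2$pct_in_library)
  # random subsets vs counting oracle
  set.seed(13)
  lib <- data.frame(gene = sprintf("g%03d", 1:60),
                    class = sample(c("mitosis", "motor", "MAP", "other"), 60, TRUE))
  for (i in 1:10) {
    hits <- sample(lib$gene, 12)
    ce3 <- class_enrichment(hits, lib)
    for (cl in ce3$class) {
      expect_equal(ce3$pct_in_hits[ce3$class == cl],
                   100 * sum(lib$class[lib$gene %in% hits] == cl) / 12,
                   tolerance = 1e-12)
      expect_equal(ce3$pct_in_library[ce3$class == cl],
                   100 * sum(lib$class == cl) / 60, tolerance = 1e-12)
    }
  }
  expect_error(class_enrichment(c("A", "nope"), ann), "nope")
})

test_that("null screens essentially never reach the 3-SD criterion", {
  # normal-theory: mean of 3 unit-SD replicate scores exceeds |3| with
  # probability 2*pnorm(-3*sqrt(3)) ~ 2e-7
  set.seed(21)
  n_genes <- 60000
  means <- rowMeans(matrix(rnorm(n_genes * 3), ncol = 3))
  expect_lte(mean(abs(means) > 3), 0.003)
  calls <- call_phenotype(mk_scores(means[1:1000], sem = 0.5))
  expect_equal(sum(calls$hit), sum(abs(means[1:1000]) > 3))
})
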