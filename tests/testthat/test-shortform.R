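test_that("criterion distribution of the reference form", {
  bank <- default_item_bank()
  ref <- default_reference_short_form(bank)
  d <- criterion_distribution(ref$item_ids, bank)
  expect_equal(unname(d["B2"]), 0.5)          # four of eight items
  expect_equal(unname(d["A"]), 0.25)          # two of eight
  expect_equal(unname(d["B1"]), 0.25)
  expect_equal(unname(d["B3"]), 0)
  expect_equal(unname(d["B4"]), 0)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_error(criterion_distribution(character(0), bank), "empty")
  expect_error(criterion_distribution("NOPE", bank), "unknown")
})

test_that("ranking comparison reproduces the published criterion coverage", {
  bank <- default_item_bank()
  ref <- default_reference_short_form(bank)
  si <- compare_rankings(published_si_ranking(), ref, bank, top_n = 10)
  # the top 10 items cover every criterion
  expect_true(all(si$ranking_proportions > 0))
  sip <- compare_rankings(published_sip_ranking(), ref, bank, top_n = 10)
  # ... except social withdrawal under the preparatory-behavior outcome
  expect_equal(unname(sip$ranking_proportions["B4"]), 0)
  expect_true(all(sip$ranking_proportions[c("A", "B1", "B2", "B3")] > 0))
  # the preparatory-behavior ranking is the closer match to the reference
  expect_gt(sip$similarity, si$similarity)
  expect_error(compare_rankings(published_si_ranking(), ref, bank, top_n = 16),
               "exceeds")
})

test_that("similarity is a bounded symmetric semimetric complement", {
  bank <- default_item_bank()
  ref <- default_reference_short_form(bank)
  # a list compared with itself: similarity 1
  self_rank <- ranking_table(1:8, ref$item_ids, rep(100L, 8),
                             bank$criterion[match(ref$item_ids, bank$item_id)])
  self <- compare_rankings(self_rank, ref, bank, top_n = 8)
  expect_equal(self$similarity, 1)
  # symmetry: swap roles via the distributions directly
  a <- compare_rankings(published_si_ranking(), ref, bank, 10)
  d1 <- 1 - 0.5 * sum(abs(a$ranking_proportions - a$reference_proportions))
  d2 <- 1 - 0.5 * sum(abs(a$reference_proportions - a$ranking_proportions))
  expect_equal(a$similarity, d1)
  expect_equal(d1, d2)
  expect_gte(a$similarity, 0); expect_lte(a$similarity, 1)
})

test_that("default quotas assemble the nine-item short form", {
  bank <- default_item_bank()
  sf <- assemble_short_form(published_si_ranking(), published_sip_ranking(),
                            bank)
  expect_equal(nrow(sf$selected), 9L)
  comp <- table(factor(sf$selected$criterion, levels = scs_criteria()))
  expect_equal(unname(as.integer(comp)), c(2L, 2L, 2L, 2L, 1L))
  expect_true(all(c("SCI-12", "SCI-4", "SCI-38", "SCI-51", "SCI-60",
                    "SCI-59", "SCI-74") %in% sf$selected$item_id))
  # everything came from the primary ranking here
  expect_true(all(sf$selected$source == "SI"))
})

test_that("missing criteria fall back to the second ranking, with source", {
  bank <- default_item_bank()
  # seed with the preparatory-behavior ranking: no B4 item in its top 15
  sf <- assemble_short_form(published_sip_ranking(), published_si_ranking(),
                            bank)
  b4 <- sf$selected[sf$selected$criterion == "B4", ]
  expect_equal(b4$item_id, "SCI-74")
  expect_equal(b4$source, "SI")               # came from the fallback
  expect_equal(b4$source_rank, 9L)
  # the rest came from the primary
  expect_true(all(sf$selected$source[sf$selected$criterion != "B4"] == "SI_P"))
  # without a fallback the same assembly fails, naming the criterion
  expect_error(assemble_short_form(published_sip_ranking(), NULL, bank),
               "criterion B4")
})

test_that("quota edge cases", {
  bank <- default_item_bank()
  empty <- assemble_short_form(published_si_ranking(), NULL, bank,
                               quotas = c(A = 0L, B1 = 0L, B2 = 0L,
                                          B3 = 0L, B4 = 0L))
  expect_equal(nrow(empty$selected), 0L)
  expect_error(assemble_short_form(published_si_ranking(), NULL, bank,
                                   quotas = c(A = 2L, ZZ = 1L)),
               "criterion tokens")
  # an unsatisfiable quota errors rather than silently shrinking
  expect_error(assemble_short_form(published_si_ranking(), NULL, bank,
                                   quotas = c(B4 = 3L)), "criterion B4")
})

test_that("assembly is deterministic and exactly fills quotas", {
  bank <- default_item_bank()
  for (q in list(c(A = 1L), c(A = 2L, B3 = 2L), c(B1 = 4L, B2 = 2L))) {
    s1 <- assemble_short_form(published_si_ranking(), published_sip_ranking(),
                              bank, quotas = q)
    s2 <- assemble_short_form(published_si_ranking(), published_sip_ranking(),
                              bank, quotas = q)
    expect_identical(s1$selected, s2$selected)
    expect_equal(nrow(s1$selected), sum(q))
    got <- table(factor(s1$selected$criterion, levels = names(q)))
    expect_equal(as.integer(got), unname(as.integer(q)))
  }
})

test_that("short forms render to CSV/Markdown and round-trip", {
  bank <- default_item_bank()
  sf <- assemble_short_form(published_si_ranking(), published_sip_ranking(),
                            bank)
  path <- tempfile(fileext = ".csv")
  render_short_form(sf, bank, "csv", path)
  back <- read_short_form(path)
  ord <- function(df) df[order(df$item_id), , drop = FALSE]
  expect_equal(ord(back$selected), ord(sf$selected), ignore_attr = TRUE)
  expect_equal(back$per_criterion_quota, sf$per_criterion_quota)
  md <- render_short_form(sf, bank, "markdown")
  expect_equal(length(md), 2 + 9)             # header + rule + nine rows
  expect_match(md[3], "^\\| A\\. Entrapment")
  # empty form: header only
  empty <- assemble_short_form(published_si_ranking(), NULL, bank,
                               quotas = c(A = 0L))
  expect_equal(render_short_form(empty, bank, "csv"),
               "criterion,criterion_name,source,source_rank,item_id,text")
})
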