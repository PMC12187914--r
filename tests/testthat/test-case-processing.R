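test_that("dedup keeps the latest fda_dt, then the largest primaryid, per caseid", {
  demo <- data.frame(
    primaryid = c("1", "2", "5", "9", "42"),
    caseid = c("7", "7", "8", "8", "3"),
    fda_dt = c("20230101", "20230301", "20230101", "20230101", "20220601"),
    stringsAsFactors = FALSE)
  kept <- deduplicate(demo)
  expect_setequal(kept, c("2", "9", "42"))
})

test_that("dedup is idempotent and retains one primaryid per caseid", {
  set.seed(11)
  n <- 400
  demo <- data.frame(
    primaryid = as.character(sample.int(10 * n, n)),
    caseid = as.character(sample.int(120, n, replace = TRUE)),
    fda_dt = format(as.Date("2015-01-01") + sample.int(3000, n, TRUE), "%Y%m%d"),
    stringsAsFactors = FALSE)
  kept <- deduplicate(demo)
  expect_equal(length(kept), length(unique(demo$caseid)))
  demo2 <- demo[demo$primaryid %in% kept, ]
  expect_setequal(deduplicate(demo2), kept)
})

test_that("partial-precision fda_dt sorts before a full date in the same month", {
  demo <- data.frame(primaryid = c("900", "2"), caseid = c("1", "1"),
                     fda_dt = c("202303", "20230301"), stringsAsFactors = FALSE)
  expect_equal(deduplicate(demo), "2")
})

test_that("synonym matching is substring, case-insensitive and accent-folded", {
  syn <- lorazepam_synonyms()
  expect_true(match_drug_name("ATIVAN 1MG TAB", syn))
  expect_true(match_drug_name("temesta", syn))
  expect_true(match_drug_name("Lorazepam Injection", syn))
  expect_false(match_drug_name("ALPRAZOLAM", syn))
  # prod_ai is searched too
  expect_true(match_drug_name("UNKNOWN BRAND", syn, prod_ai = "LORAZEPAM"))
})

test_that("adding a synonym never removes a matched report", {
  drug <- data.frame(primaryid = c("1", "2", "3"), drug_seq = 1L,
                     role_cod = "PS",
                     drugname = c("ATIVAN", "DONIX", "ZZZ-DRUG"),
                     prod_ai = "", stringsAsFactors = FALSE)
  retained <- c("1", "2", "3")
  small <- synonym_list("ATIVAN")
  big <- synonym_list(c("ATIVAN", "DONIX"))
  s1 <- select_primary_suspect(drug, retained, small)
  s2 <- select_primary_suspect(drug, retained, big)
  expect_true(all(s1 %in% s2))
})

test_that("only primary-suspect role qualifies a report", {
  drug <- data.frame(
    primaryid = c("10", "11", "12", "12"), drug_seq = c(1L, 1L, 1L, 2L),
    role_cod = c("SS", "PS", "PS", "PS"),
    drugname = c("ATIVAN", "ATIVAN", "IBUPROFEN", "LORAZ TAB"),
    prod_ai = "", stringsAsFactors = FALSE)
  got <- select_primary_suspect(drug, c("10", "11", "12"), lorazepam_synonyms())
  expect_setequal(got, c("11", "12"))  # SS-only report excluded
})

test_that("age conversion covers every unit code", {
  expect_equal(convert_age(5, "DEC"), 50)
  expect_equal(convert_age(24, "MON"), 2)
  expect_equal(convert_age(730.5, "DY"), 2)
  expect_equal(convert_age(52.1775, "WK"), 1)
  expect_equal(convert_age(8766, "HR"), 1)
  expect_true(is.na(convert_age(5, "XX")))
  expect_true(is.na(convert_age(-1, "YR")))
})

test_that("age bands are half-open and partition", {
  expect_equal(assign_age_band(c(17.9, 18, 64.99, 65, 90, NA)),
               c("<18", "18-65", "18-65", ">=65", ">=65", "unknown"))
})

test_that("PT to SOC lookup normalises and falls back to 'unmapped'", {
  m <- test_map()
  expect_equal(map_pt_to_soc("Sopor", m), "Psychiatric disorders")
  expect_equal(map_pt_to_soc("Somnolence", m), "Nervous system disorders")
  expect_equal(map_pt_to_soc("  sopor ", m), "Psychiatric disorders")
  expect_equal(map_pt_to_soc("Never seen", m), "unmapped")
})

test_that("case assembly deduplicates PTs within a report and flags targets", {
  demo <- data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                     fda_dt = "20230101", event_dt = "", sex = c("F", "M"),
                     age = c(40, NA), age_cod = c("YR", ""),
                     occr_country = "US", occp_cod = "MD",
                     stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = c("1", "2"), drug_seq = 1L,
                     role_cod = "PS", drugname = c("ATIVAN", "IBUPROFEN"),
                     prod_ai = "", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "1", "1", "2"),
                     pt = c("Sopor", "Sopor", "Nausea", "Nausea"),
                     stringsAsFactors = FALSE)
  cases <- build_case_reports(list(demo = demo, drug = drug, reac = reac), lorazepam_synonyms())
  expect_equal(nrow(cases), 2)
  expect_equal(sort(cases$reaction_pts[[match("1", cases$primaryid)]]),
               c("Nausea", "Sopor"))
  expect_equal(cases$is_target, c(TRUE, FALSE)[match(cases$primaryid, c("1", "2"))])
  expect_equal(attr(cases, "flow")[["target_reports"]], 1L)
})

test_that("therapy_start is the earliest full-precision PS start date", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = "20230601",
                     event_dt = "20230301", sex = "F", age = 40, age_cod = "YR",
                     occr_country = "", occp_cod = "", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = c("1", "1", "1"), drug_seq = c(1L, 2L, 3L),
                     role_cod = c("PS", "PS", "C"),
                     drugname = c("ATIVAN", "LORAZ", "ASPIRIN"),
                     prod_ai = "", stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = c("1", "1", "1"), dsg_drug_seq = c(1L, 2L, 3L),
                     start_dt = c("20230215", "202301", "20220101"),
                     end_dt = "", stringsAsFactors = FALSE)
  cases <- build_case_reports(list(demo = demo, drug = drug,
                                   reac = NULL, ther = ther), lorazepam_synonyms())
  # seq 2 start has only YM precision and seq 3 is concomitant: seq 1 wins
  expect_equal(cases$therapy_start, "20230215")
})
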