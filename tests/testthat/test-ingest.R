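test_that("FAERS dialect round-trips through write and read", {
  cfg <- small_config(missing_age_rate = 0.3, partial_date_rate = 0.2)
  b <- generate_bundle(cfg)
  dir <- withr::local_tempdir()
  write_faers_dialect(b, dir, quarter = "24Q3")
  demo <- read_faers_table(file.path(dir, "DEMO24Q3.txt"), "demo")
  expect_equal(demo$PRIMARYID, b$demo$PRIMARYID)
  expect_equal(demo$FDA_DT, b$demo$FDA_DT)
  expect_equal(demo$SEX, b$demo$SEX)
  expect_equal(as.numeric(demo$AGE), b$demo$AGE) # empty fields come back as NA
  reac <- read_faers_table(file.path(dir, "REAC24Q3.txt"), "reac")
  expect_equal(reac$PT, b$reac$PT)
  bundle <- read_faers_bundle(dir)
  expect_equal(nrow(bundle$outc), nrow(b$outc))
})

test_that("header-only and malformed files are handled", {
  dir <- withr::local_tempdir()
  # an empty table writes as a header-only file and reads back empty
  b <- generate_bundle(small_config(serious_rate = 0))
  expect_equal(nrow(b$outc), 0)
  write_faers_dialect(b, dir, quarter = "24Q3")
  expect_equal(readLines(file.path(dir, "OUTC24Q3.txt")), "PRIMARYID$OUTC_COD")
  f <- file.path(dir, "OUTC24Q3.txt")
  tab <- read_faers_table(f, "outc")
  expect_equal(nrow(tab), 0)
  # trailing delimiter leaves an empty final field, read as missing
  writeLines(c("PRIMARYID$OUTC_COD", "45$"), f)
  trailing <- read_faers_table(f, "outc")
  expect_equal(trailing$PRIMARYID, "45")
  expect_true(is.na(trailing$OUTC_COD))
  writeLines(c("PRIMARYID$WRONG", "1$x"), f)
  expect_error(read_faers_table(f, "outc"), "OUTC_COD")
  expect_error(read_faers_table(file.path(dir, "absent.txt"), "demo"),
               "not found")
})

test_that("partial dates parse by the 8/6/4-digit policy", {
  expect_equal(parse_partial_date("20200310"), as.Date("2020-03-10"))
  expect_equal(parse_partial_date("202003"), as.Date("2020-03-01"))
  expect_true(is.na(parse_partial_date("2020")))
  expect_true(is.na(parse_partial_date("")))
  expect_true(is.na(parse_partial_date("notadate")))
  expect_equal(partial_date_year(c("2020", "202003", "20200310", "", "x")),
               c(2020L, 2020L, 2020L, NA, NA))
})

test_that("deduplication keeps latest FDA_DT then largest PRIMARYID, and is idempotent", {
  demo <- tibble::tibble(
    PRIMARYID = c("10", "11", "5", "9", "2"),
    CASEID = c("1", "1", "2", "2", "3"),
    FDA_DT = c("20200101", "20200301", "20200101", "20200101", "20200601")
  )
  out <- deduplicate_demo(demo)
  expect_equal(out$PRIMARYID[out$CASEID == "1"], "11") # latest FDA_DT
  expect_equal(out$PRIMARYID[out$CASEID == "2"], "9")  # tie -> largest id
  expect_equal(nrow(out), 3)
  expect_identical(deduplicate_demo(out), out)
  # all-unique input passes through (sorted by CASEID)
  uniq <- demo[c(1, 3, 5), ]
  expect_equal(nrow(deduplicate_demo(uniq)), 3)
})

test_that("dedup survivors match the generator manifest exactly", {
  cfg <- small_config(duplicate_rate = 0.15)
  b <- generate_bundle(cfg)
  out <- deduplicate_demo(b$demo)
  dups <- b$manifest$duplicates
  expect_equal(out$PRIMARYID[match(dups$caseid, out$CASEID)],
               dups$survivor_primaryid)
  expect_equal(nrow(out), b$manifest$n_reports)
})

test_that("linking drops reaction-less reports and takes the earliest therapy start", {
  demo <- tibble::tibble(
    PRIMARYID = c("1", "2"), CASEID = c("1", "2"),
    FDA_DT = "20200601", EVENT_DT = "20200310", SEX = "F", AGE = "50",
    AGE_COD = "YR", REPORTER_COUNTRY = "US", OCCP_COD = "MD"
  )
  drug <- tibble::tibble(PRIMARYID = c("1", "1", "2"), DRUG_SEQ = c("1", "2", "1"),
                         DRUGNAME = "TARGET", ROLE_COD = c("PS", "SS", "PS"))
  reac <- tibble::tibble(PRIMARYID = c("1", "1"), PT = c("Myalgia", "Gout"))
  ther <- tibble::tibble(PRIMARYID = c("1", "1"), DSG_DRUG_SEQ = c("1", "2"),
                         START_DT = c("20200305", "20200101"),
                         END_DT = NA_character_)
  outc <- tibble::tibble(PRIMARYID = "1", OUTC_COD = "HO")
  expect_message(
    reports <- link_reports(demo, drug, reac, ther, outc, "Target"),
    "dropped 1"
  )
  expect_equal(nrow(reports), 1)
  expect_equal(sort(reports$reactions[[1]]), c("GOUT", "MYALGIA"))
  expect_equal(reports$therapy_start, as.Date("2020-01-01"))
  expect_true(reports$serious)
})

test_that("cohort selection filters on normalized name and role code, partitioning input", {
  demo <- tibble::tibble(
    PRIMARYID = as.character(1:3), CASEID = as.character(1:3),
    FDA_DT = "20200601", EVENT_DT = "20200310", SEX = "F", AGE = "50",
    AGE_COD = "YR", REPORTER_COUNTRY = "US", OCCP_COD = "MD"
  )
  drug <- tibble::tibble(
    PRIMARYID = c("1", "2", "3"), DRUG_SEQ = "1",
    DRUGNAME = c("  fenofibric   acid ", "FENOFIBRIC ACID", "OTHER"),
    ROLE_COD = c("PS", "C", "PS")
  )
  reac <- tibble::tibble(PRIMARYID = as.character(1:3), PT = "Myalgia")
  ther <- tibble::tibble(PRIMARYID = character(), DSG_DRUG_SEQ = character(),
                         START_DT = character(), END_DT = character())
  outc <- tibble::tibble(PRIMARYID = character(), OUTC_COD = character())
  reports <- link_reports(demo, drug, reac, ther, outc, "FENOFIBRIC ACID")
  sp <- primary_suspect_cohort(reports, "Fenofibric Acid ")
  expect_equal(sp$cohort$primaryid, "1") # concomitant use does not qualify
  expect_equal(sort(sp$background$primaryid), c("2", "3"))
  expect_equal(nrow(sp$cohort) + nrow(sp$background), nrow(reports))
  none <- primary_suspect_cohort(reports, "ABSENT DRUG")
  expect_equal(nrow(none$cohort), 0)
  expect_equal(nrow(none$background), nrow(reports))
})

test_that("synthetic cohort size tracks the configured drug probability", {
  core <- run_core(synthetic_config(n_reports = 5000, seed = 2,
                                    duplicate_rate = 0))
  frac <- nrow(core$cohort) / 5000
  expect_lt(abs(frac - 0.10), 4 * sqrt(0.1 * 0.9 / 5000))
})
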