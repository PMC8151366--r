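test_that("morpho-species mapping groups congeners and rejects unknown names", {
  expect_equal(map_morphospecies("Bombus fervidus"), "B. borealis group")
  expect_equal(map_morphospecies("Bombus impatiens"), "B. impatiens")
  expect_equal(map_morphospecies("Bombus vagans"), "B. vagans group")
  expect_equal(map_morphospecies("Bombus perplexus"), "B. vagans group")
  expect_equal(map_morphospecies("B. ternarius"), "B. ternarius")  # abbreviated form
  expect_equal(map_morphospecies(c("Bombus borealis", "Bombus citrinus")),
               c("B. borealis group", "B. citrinus"))
  expect_length(morphospecies_groups(), 8)
  expect_error(map_morphospecies("Bombus lucorum"), "Bombus lucorum")
})

test_that("survey-effort arithmetic multiplies the design factors", {
  expect_equal(compute_effort(3, 2, 2, 1), 12)
  expect_equal(compute_effort(1, 1, 1, 1), 1)
  expect_equal(compute_effort(3, 1, 2, 0.5), 3)
  expect_error(compute_effort(0, 2, 2, 1), "visits")
  expect_error(compute_effort(3, 2, 2, -1), "positive")
})

make_visits <- function() {
  expand.grid(visit = 1:3, site_id = 4:5, season_id = c("spring-2017", "fall-2017"),
              stringsAsFactors = FALSE)[, c("site_id", "season_id", "visit")] |>
    transform(air_temp = 15, time_of_day = 5)
}
make_sites <- function() data.frame(site_id = 4:5, enhancement = c(1, 0),
                                    pesticide_index = c(20, 60))

test_that("detection histories collapse counts, merge groups, and fill absences", {
  records <- data.frame(
    site_id = c(4, 4, 4, 4),
    season_id = c("spring-2017", "spring-2017", "spring-2017", "spring-2017"),
    visit = c(2, 2, 2, 1),
    taxon = c("Bombus impatiens", "Bombus impatiens", "Bombus perplexus", "Bombus vagans"),
    count = c(3, 2, 1, 1),
    stringsAsFactors = FALSE
  )
  d <- build_detection_history(records, make_visits(), make_sites())
  expect_s3_class(d, "detection_dataset")
  expect_equal(dim(d$y), c(8, 4, 3))
  imp <- which(d$species == "B. impatiens")
  vag <- which(d$species == "B. vagans group")
  cit <- which(d$species == "B. citrinus")
  u <- which(d$units$site_id == 4 & d$units$season_id == "spring-2017")
  expect_equal(d$y[imp, u, 2], 1)            # any count >= 1 collapses to 1
  expect_equal(d$y[vag, u, ], c(1, 1, 0))    # two group members merge to one row
  expect_equal(d$y[cit, u, ], c(0, 0, 0))    # absence of records -> all-zero history
  # pesticide classified from the raw index at the default threshold
  expect_equal(d$units$pesticide_high[d$units$site_id == 4][1], 0)
  expect_equal(d$units$pesticide_high[d$units$site_id == 5][1], 1)
  # collapsing is idempotent: rebuilding from the binary records changes nothing
  idx <- which(d$y == 1, arr.ind = TRUE)
  bin <- data.frame(site_id = d$units$site_id[idx[, 2]],
                    season_id = d$units$season_id[idx[, 2]],
                    visit = idx[, 3], taxon = NA, count = 1)
  rep_taxon <- c("B. borealis group" = "Bombus borealis",
                 "B. bimaculatus group" = "Bombus bimaculatus",
                 "B. vagans group" = "Bombus vagans",
                 "B. citrinus" = "Bombus citrinus",
                 "B. impatiens" = "Bombus impatiens",
                 "B. rufocinctus" = "Bombus rufocinctus",
                 "B. ternarius" = "Bombus ternarius",
                 "B. terricola" = "Bombus terricola")
  bin$taxon <- unname(rep_taxon[d$species[idx[, 1]]])
  d2 <- build_detection_history(bin, make_visits(), make_sites())
  expect_identical(d2$y, d$y)
})

test_that("column sums of y equal the number of cells with at least one capture", {
  set.seed(42)
  visits <- make_visits()
  taxa <- c("Bombus impatiens", "Bombus ternarius", "Bombus vagans", "Bombus sandersoni")
  records <- data.frame(
    site_id = sample(4:5, 30, TRUE),
    season_id = sample(c("spring-2017", "fall-2017"), 30, TRUE),
    visit = sample(1:3, 30, TRUE),
    taxon = sample(taxa, 30, TRUE),
    count = rpois(30, 2),
    stringsAsFactors = FALSE
  )
  d <- build_detection_history(records, visits, make_sites())
  grp <- map_morphospecies(records$taxon)
  for (g in unique(grp)) {
    sub <- records[grp == g & records$count >= 1, ]
    cells <- unique(paste(sub$site_id, sub$season_id, sub$visit))
    expect_equal(sum(d$y[which(d$species == g), , ]), length(cells))
  }
})

test_that("invalid records are rejected and missing covariates flagged", {
  visits <- make_visits()
  rec <- data.frame(site_id = 4, season_id = "spring-2017", visit = 9,
                    taxon = "Bombus impatiens", count = 1)
  expect_error(build_detection_history(rec, visits, make_sites()), "undeclared visit")
  rec$visit <- 1; rec$site_id <- 99
  expect_error(build_detection_history(rec, visits, make_sites()), "undeclared")
  visits$air_temp[2] <- NA
  d <- build_detection_history(rec[0, ], visits, make_sites())
  expect_match(d$flags, "missing covariate", all = FALSE)
})

test_that("clock time plus sunrise converts to hours after sunrise", {
  visits <- make_visits()
  visits$time_of_day <- NULL
  visits$clock_time <- 11.5
  visits$sunrise <- 5.5
  d <- build_detection_history(data.frame(site_id = numeric(0), season_id = character(0),
                                          visit = numeric(0), taxon = character(0),
                                          count = numeric(0)),
                               visits, make_sites())
  # all time values identical -> standardized column is all zero
  expect_true(all(abs(d$time) < 1e-12))
  expect_equal(d$scaling$time_mean, 6)
})

test_that("writing and re-reading a dataset reproduces it exactly", {
  sim <- generate_community_dataset(community_truth(n_sites = 4, n_spring = 2,
                                                    n_fall = 1), seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".json")
  write_detection_data(sim$data, csv, side)
  d2 <- read_detection_data(csv, side)
  expect_identical(d2$y, sim$data$y)
  expect_equal(d2$air, sim$data$air, tolerance = 1e-15)
  expect_equal(d2$time, sim$data$time, tolerance = 1e-15)
  expect_equal(d2$scaling, sim$data$scaling, tolerance = 1e-15)
  expect_equal(d2$units$site_index, sim$data$units$site_index)
})

test_that("ragged designs (unequal visit numbers) are accepted", {
  y <- array(c(1, 0, NA, 0, 1, 0), c(1, 2, 3))
  units <- data.frame(site_id = 1:2, season_id = "spring-1", season_fall = 0,
                      enhancement = 0:1, pesticide_high = c(1, 0))
  air <- matrix(c(12, 14, NA, 15, 13, 11), 2, 3)
  tod <- matrix(c(2, 3, NA, 4, 5, 6), 2, 3)
  d <- detection_dataset(y, "sp1", units, air, tod)
  expect_equal(sum(d$obs), 5)
  expect_error(detection_dataset(array(NA_real_, c(1, 2, 3)), "sp1", units, air, tod),
               "no observed visits")
})
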