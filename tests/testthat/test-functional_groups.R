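make_table <- function(abundance, taxa) {
  n <- nrow(abundance)
  samples <- data.frame(site = "s",
                        date = seq(as.Date("2020-01-15"), by = "month",
                                   length.out = n))
  phyto_abundance(samples, taxa, abundance)
}

test_that("taxa are classified by name against the catalog", {
  taxa <- data.frame(
    taxon_id = c("a", "b", "c", "d"),
    name = c("Cyclotella sp.", "Pseudanabaena limnetica",
             "Unknownella mysteriosa", "Peridinium umbonatum"),
    phylum = c("Bacillariophyta", "Cyanophyta", "Chlorophyta", "Dinophyta"),
    cell_volume_um3 = c(1200, 30, 100, 9000),
    fg_code = NA_character_
  )
  tab <- make_table(matrix(1e5, 2, 4), taxa)
  expect_message(cls <- classify_taxa(tab), "1 taxa unassigned")
  expect_equal(cls$taxa$fg_code, c("B", "S1", "UNASSIGNED", "L_O"))

  # an explicit metadata code wins over the name match
  taxa$fg_code <- c("MP", NA, NA, NA)
  tab2 <- make_table(matrix(1e5, 2, 4), taxa)
  cls2 <- suppressMessages(classify_taxa(tab2))
  expect_equal(cls2$taxa$fg_code[1], "MP")
})

test_that("biomass conversion follows the biovolume formula and sums by group", {
  taxa <- data.frame(
    taxon_id = c("x", "y", "z"),
    name = c("A sp.", "B sp.", "C sp."),
    phylum = "Chlorophyta",
    cell_volume_um3 = c(1000, 500, 250),
    fg_code = c("J", "B", "B")
  )
  # volume 1000 um3 at 1e6 cells/L -> 1.0 mg/L
  ab <- matrix(c(1e6, 1e6, 1e6), 1, 3)
  bm <- compute_biomass(make_table(ab, taxa))
  expect_equal(unname(bm$biomass[1, "J"]), 1.0)
  # two taxa in group B at 0.5 and 0.25 mg/L -> 0.75
  expect_equal(unname(bm$biomass[1, "B"]), 0.75)
  expect_equal(unname(rowSums(bm$relative)), 1)

  # conservation: group partition preserves the taxon-level total
  per_taxon_total <- sum(ab %*% diag(taxa$cell_volume_um3) * 1e-9)
  expect_equal(sum(bm$biomass), per_taxon_total)

  expect_error(compute_biomass(make_table(ab, transform(taxa, fg_code = NA))),
               "classify_taxa")
})

test_that("dominance index matches its definition and thresholds", {
  taxa <- data.frame(taxon_id = "only", name = "Only sp.", phylum = "Chlorophyta",
                     cell_volume_um3 = 100, fg_code = "J")
  tab <- make_table(matrix(c(10, 20, 30), 3, 1), taxa)
  d <- dominance(tab)
  expect_equal(d$Y, 1)  # sole taxon present everywhere
  expect_equal(as.character(d$status), "absolute_dominant")

  # share 0.5, fi 0.5 -> Y = 0.25 -> absolute dominant
  taxa2 <- data.frame(taxon_id = c("a", "b"), name = c("A sp.", "B sp."),
                      phylum = "Chlorophyta", cell_volume_um3 = 100,
                      fg_code = "J")
  m <- matrix(c(10, 0, 5, 5), 2, 2)  # taxon a: 10 in sample1 only; b: 5 and 5
  d2 <- dominance(make_table(m, taxa2))
  a_row <- d2[d2$taxon_id == "a", ]
  expect_equal(a_row$share, 0.5)
  expect_equal(a_row$fi, 0.5)
  expect_equal(a_row$Y, 0.25)
  expect_equal(as.character(a_row$status), "absolute_dominant")
})

test_that("dominance equals the brute-force oracle on random matrices", {
  set.seed(42)
  for (rep in 1:100) {
    ns <- sample(2:10, 1)
    nt <- sample(2:10, 1)
    m <- matrix(rexp(ns * nt) * rbinom(ns * nt, 1, 0.7), ns, nt)
    m[, 1] <- rexp(ns) + 0.1  # every sample has a positive entry
    taxa <- data.frame(taxon_id = paste0("t", seq_len(nt)),
                       name = paste0("T", seq_len(nt), " sp."),
                       phylum = "Chlorophyta", cell_volume_um3 = 100,
                       fg_code = "J")
    tab <- make_table(m, taxa)
    d <- dominance(tab)
    expect_equal(d$Y[match(taxa$taxon_id, d$taxon_id)],
                 oracle_dominance_Y(m), tolerance = 1e-12)
  }
})

test_that("Y is monotone in a taxon's own abundance", {
  set.seed(7)
  taxa <- data.frame(taxon_id = paste0("t", 1:4),
                     name = paste0("T", 1:4, " sp."), phylum = "Chlorophyta",
                     cell_volume_um3 = 100, fg_code = "J")
  for (rep in 1:50) {
    m <- matrix(rexp(20), 5, 4)
    y0 <- dominance(make_table(m, taxa))
    m2 <- m
    m2[2, 3] <- m2[2, 3] * 3 + 1
    y1 <- dominance(make_table(m2, taxa))
    expect_gte(y1$Y[y1$taxon_id == "t3"], y0$Y[y0$taxon_id == "t3"])
  }
})

test_that("dominant functional groups use aggregated shares and a strict 5% rule", {
  taxa <- data.frame(
    taxon_id = paste0("t", 1:4),
    name = paste0("T", 1:4, " sp."), phylum = "Chlorophyta",
    cell_volume_um3 = 1000,
    fg_code = c("B", "D", "J", "Y")
  )
  # shares 60/30/6/4 by construction (equal volumes)
  m <- matrix(c(60, 30, 6, 4) * 1e4, 1, 4)
  bm <- compute_biomass(make_table(m, taxa))
  dg <- dominant_groups(bm)
  expect_equal(dg$code, c("B", "D", "J"))
  expect_equal(dg$share, c(0.6, 0.3, 0.06))
  expect_equal(sum(dg$share) + attr(dg, "others"), 1, tolerance = 1e-9)

  # single group
  taxa1 <- taxa[1, ]
  bm1 <- compute_biomass(make_table(matrix(1e5, 1, 1), taxa1))
  dg1 <- dominant_groups(bm1)
  expect_equal(dg1$code, "B")
  expect_equal(dg1$share, 1)
})

test_that("scaling abundance scales biomass but leaves shares, Y and SR inputs alone", {
  set.seed(11)
  taxa <- data.frame(taxon_id = paste0("t", 1:5),
                     name = paste0("T", 1:5, " sp."), phylum = "Chlorophyta",
                     cell_volume_um3 = runif(5, 50, 5000),
                     fg_code = c("B", "B", "D", "J", "Y"))
  m <- matrix(rexp(20) * 1e4, 4, 5)
  tab <- make_table(m, taxa)
  tab_scaled <- make_table(m * 3.7, taxa)
  bm <- compute_biomass(tab)
  bm_s <- compute_biomass(tab_scaled)
  expect_equal(bm_s$biomass, bm$biomass * 3.7)
  expect_equal(bm_s$relative, bm$relative)
  expect_equal(dominance(tab_scaled)$Y, dominance(tab)$Y)
  expect_equal(dominant_groups(bm_s), dominant_groups(bm), ignore_attr = TRUE)
})

test_that("habitat indication returns catalog text verbatim", {
  cat27 <- fg_catalog()
  hb <- habitat_indication(c("B", "Y"), cat27)
  expect_equal(hb$habitat[1],
               "Mesotrophic trophic, small-to-medium, or large shallow-water bodies")
  expect_equal(hb$habitat[2], "Still-water environment")
  expect_equal(nrow(habitat_indication(character(0), cat27)), 0)
  expect_error(habitat_indication("Q99", cat27), "unknown")
})

test_that("composition summary counts present taxa and rounds half-up", {
  taxa <- data.frame(taxon_id = paste0("t", 1:3),
                     name = paste0("T", 1:3, " sp."), phylum = "Chlorophyta",
                     cell_volume_um3 = 100, fg_code = "J")
  cs <- composition_summary(make_table(matrix(c(1, 1, 1), 1, 3), taxa))
  expect_equal(cs$pct, 100)
  expect_equal(attr(cs, "total"), 3)

  # a taxon with zero abundance everywhere does not count
  m <- matrix(c(5, 5, 0), 1, 3)
  cs2 <- composition_summary(make_table(m, taxa))
  expect_equal(attr(cs2, "total"), 2)
})
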