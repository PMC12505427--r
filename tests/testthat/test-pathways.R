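test_that("catalog loading validates structure and round trips", {
  catalog <- load_catalog()
  expect_s3_class(catalog, "pathway_catalog")
  expect_length(catalog$pathways, 13)  # 10 EAA + Cys + riboflavin + biotin
  expect_equal(sum(vapply(catalog$pathways,
                          function(p) p$class == "EAA", TRUE)), 10)
  # round trip through save/load is the identity
  tf <- tempfile(fileext = ".tsv")
  save_catalog(catalog, tf)
  back <- load_catalog(tf)
  expect_equal(back$pathways, catalog$pathways)

  expect_error(new_catalog(list(
    list(pathway_id = "a", display_name = "a", class = "EAA",
         steps = list("x")),
    list(pathway_id = "a", display_name = "a", class = "EAA",
         steps = list("y")))), "duplicate")
  expect_error(new_catalog(list(
    list(pathway_id = "a", display_name = "a", class = "nope",
         steps = list("x")))), "class")
  expect_error(new_catalog(list(
    list(pathway_id = "a", display_name = "a", class = "EAA",
         steps = list(character(0))))), "empty step")
})

test_that("presence profiling resolves synonyms and split genes", {
  catalog <- mini_catalog()
  feats <- new_feature_set(data.frame(
    genome_id = "gA",
    locus_tag = c("t1", "t2", "t3", "t4a", "t4b"),
    segment = 1L,
    start = c(0L, 100L, 200L, 300L, 340L),
    end = c(90L, 190L, 290L, 330L, 390L),
    strand = "+", type = "CDS",
    gene = c("g1", "G2SYN", "h1", "g3", "g3"),  # case-insensitive synonym
    product = NA_character_,
    pseudo = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE))
  merged <- data.frame(genome_id = "gA", gene = "g3",
                       first_locus_tag = "t4a", second_locus_tag = "t4b",
                       stringsAsFactors = FALSE)
  pres <- profile_presence(feats, merged, catalog)
  expect_equal(pres["gA", "g1"], "present")
  expect_equal(pres["gA", "g2alt"], "present")   # via synonym map
  expect_equal(pres["gA", "h1"], "absent")       # pseudo CDS do not count
  expect_equal(pres["gA", "g3"], "present_split")
})

test_that("completeness counts covered steps with alternatives", {
  catalog <- mini_catalog()
  pres <- presence_from_list(list(gA = c("g1", "g2alt"),
                                  gB = c("h1", "h2")), catalog)
  comp <- completeness(pres, catalog)
  a1 <- comp[comp$genome == "gA" & comp$pathway_id == "p1", ]
  expect_equal(a1$covered_steps, 2)     # g2alt satisfies the g2/g2alt step
  expect_equal(a1$completeness, 2 / 3)
  expect_equal(unlist(a1$missing), "g3")
  b2 <- comp[comp$genome == "gB" & comp$pathway_id == "p2", ]
  expect_equal(b2$completeness, 1)
  # empty presence -> completeness 0 everywhere
  none <- presence_from_list(list(gC = character(0)), catalog)
  expect_true(all(completeness(none, catalog)$completeness == 0))
})

test_that("consortium union covers a step when any member covers it", {
  catalog <- mini_catalog()
  pres <- presence_from_list(list(gA = c("g1"), gB = c("g2", "g3")),
                             catalog)
  comp <- completeness(pres, catalog)
  cons <- consortium_union(comp, whitelist = character(0),
                           catalog = catalog)
  p1 <- cons[cons$pathway_id == "p1", ]
  expect_equal(p1$union_completeness, 1)
  expect_true(p1$jointly_complete)
  expect_equal(p1$n_sole_provider_steps, 3)  # each step has one provider
  # union of a single genome equals its own report
  solo <- consortium_union(completeness(pres["gA", , drop = FALSE],
                                        catalog),
                           whitelist = character(0), catalog = catalog)
  expect_equal(solo$union_completeness[solo$pathway_id == "p1"], 1 / 3)
  # idempotence: a duplicated report does not change the union
  dup <- consortium_union(list(comp, comp), whitelist = character(0),
                          catalog = catalog)
  expect_equal(dup$union_completeness, cons$union_completeness)
  expect_equal(dup$n_sole_provider_steps, cons$n_sole_provider_steps)
  # mismatched catalogs are rejected
  other <- new_catalog(list(list(pathway_id = "q", display_name = "q",
                                 class = "EAA", steps = list("z"))))
  expect_error(consortium_union(comp, catalog = other), "same catalog")
})

test_that("union completeness is monotone in consortium membership", {
  catalog <- mini_catalog()
  set.seed(97)
  vocab <- endosym:::catalog_symbols(catalog)
  for (rep_i in 1:20) {
    lst <- lapply(1:3, function(i) sample(vocab, sample(0:4, 1)))
    names(lst) <- paste0("g", 1:3)
    pres <- presence_from_list(lst, catalog)
    comp_all <- completeness(pres, catalog)
    cons_all <- consortium_union(comp_all, whitelist = character(0),
                                 catalog = catalog)
    for (g in names(lst)) {
      solo <- completeness(pres[g, , drop = FALSE], catalog)
      # union >= every member, pathway by pathway
      expect_true(all(cons_all$union_completeness >=
                      solo$completeness[match(cons_all$pathway_id,
                                              solo$pathway_id)]))
    }
    cons_two <- consortium_union(
      completeness(pres[c("g1", "g2"), , drop = FALSE], catalog),
      whitelist = character(0), catalog = catalog)
    expect_true(all(cons_all$union_completeness >=
                    cons_two$union_completeness))
  }
})

test_that("whitelist enlargement never revokes joint completeness", {
  catalog <- mini_catalog()
  pres <- presence_from_list(list(gA = c("g1", "g3"), gB = "h1"), catalog)
  comp <- completeness(pres, catalog)
  small <- consortium_union(comp, whitelist = "g2", catalog = catalog)
  big <- consortium_union(comp, whitelist = c("g2", "g2alt", "h2"),
                          catalog = catalog)
  expect_true(all(big$jointly_complete >= small$jointly_complete))
  # a step whose alternatives are only partially whitelisted still blocks
  expect_false(small$jointly_complete[small$pathway_id == "p1"])
  full <- consortium_union(comp, whitelist = c("g2", "g2alt"),
                           catalog = catalog)
  expect_true(full$jointly_complete[full$pathway_id == "p1"])
})

test_that("the shipped consortium fixture splits labour as published", {
  catalog <- load_catalog()
  pres <- read_presence(system.file("extdata", "consortium_presence.tsv",
                                    package = "endosym"), catalog)
  comp <- completeness(pres, catalog)
  eaa <- comp[comp$class == "EAA", ]
  retained <- tapply(eaa$covered_steps > 0, eaa$genome, sum)
  # branched-chain amino acids in Karelsulcia, the other 7 in Vidania
  expect_equal(as.vector(retained[c("Karelsulcia_CW", "Karelsulcia_PL")]),
               c(3, 3))
  expect_equal(as.vector(retained[c("Vidania_CW", "Vidania_PL")]), c(7, 7))
  k_pathways <- unique(eaa$pathway_id[eaa$genome == "Karelsulcia_PL" &
                                      eaa$covered_steps > 0])
  expect_setequal(k_pathways, c("leucine", "isoleucine", "valine"))
})
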