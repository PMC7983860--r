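test_that("build_network validates structure and rejects malformed inputs", {
  net <- make_sample_network()
  expect_s3_class(net, "cerna_network")
  expect_equal(nrow(net$genes) + nrow(net$mirnas), 8L)
  expect_equal(nrow(net$edges), 7L)
  expect_equal(sum(net$edges$gene == "G4"), 2L)  # G4 bridges both miRNAs

  genes <- data.frame(id = c("G1", "G2"), expression = c(10, 20))
  mirnas <- data.frame(id = "M1", expression = 5)

  # empty edge table: no miRNA has targets
  expect_error(build_network(genes, mirnas,
                             data.frame(mirna = character(), gene = character())),
               "empty")
  # duplicate edge
  expect_error(build_network(genes, mirnas,
                             data.frame(mirna = c("M1", "M1"),
                                        gene = c("G1", "G1"))),
               "duplicate")
  # unknown endpoint
  expect_error(build_network(genes, mirnas,
                             data.frame(mirna = "M1", gene = "G9")),
               "unknown gene")
  # negative expression
  expect_error(build_network(data.frame(id = "G1", expression = -1),
                             mirnas, data.frame(mirna = "M1", gene = "G1")),
               "negative")
  # isolated miRNA rejected by default, droppable on request
  m2 <- data.frame(id = c("M1", "M2"), expression = c(5, 5))
  e1 <- data.frame(mirna = "M1", gene = "G1")
  expect_error(build_network(genes, m2, e1), "no targets")
  expect_warning(net2 <- build_network(genes, m2, e1,
                                       drop_isolated_mirnas = TRUE),
                 "dropping")
  expect_equal(net2$mirnas$id, "M1")
  # duplicated id across classes
  expect_error(build_network(genes,
                             data.frame(id = "G1", expression = 5),
                             data.frame(mirna = "G1", gene = "G2")),
               "unique")
})

test_that("factor normalization maps the strongest factor to 1", {
  genes <- data.frame(id = c("G1", "G2"), expression = c(100, 100))
  mirnas <- data.frame(id = "M1", expression = 10)
  edges <- data.frame(mirna = "M1", gene = c("G1", "G2"),
                      energy = c(-20, -10))
  net <- build_network(genes, mirnas, edges)
  expect_equal(net$edges$energy_norm, c(1, 0.5))
  expect_equal(net$edges$affinity, c(1, 0.5))

  # positive energies are invalid
  edges$energy <- c(5, -10)
  expect_error(build_network(genes, mirnas, edges), "<= 0")

  # constant seed column is uninformative -> all 1 with a warning
  edges2 <- data.frame(mirna = "M1", gene = c("G1", "G2"),
                       seed_type_effect = c(1, 1))
  expect_warning(net2 <- build_network(genes, mirnas, edges2), "constant")
  expect_equal(net2$edges$seed_norm, c(1, 1))

  # missing factor on some edges only defaults that edge to neutral
  edges3 <- data.frame(mirna = "M1", gene = c("G1", "G2"),
                       energy = c(-20, NA))
  net3 <- build_network(genes, mirnas, edges3)
  expect_equal(net3$edges$energy_norm, c(1, 1))

  # absent factors leave every affinity neutral
  net4 <- build_network(genes, mirnas,
                        data.frame(mirna = "M1", gene = c("G1", "G2")))
  expect_equal(net4$edges$affinity, c(1, 1))
})

test_that("miRNA distributes in proportion to affinity-weighted target expression", {
  net <- star_network(c(10000, 10000, 5000, 10000), mirna_expr = 1000)
  rv <- distribute_mirna(net)
  expect_equal(rv$edge_rc$rc,
               c(2000 / 7, 2000 / 7, 1000 / 7, 2000 / 7), tolerance = 1e-12)
  expect_equal(round(rv$edge_rc$rc), c(286, 286, 143, 286))

  # doubling one target's expression pulls repression toward it
  rv2 <- distribute_mirna(net, gene_expressions = c(G2 = 20000))
  expect_equal(rv2$edge_rc$rc,
               c(2000 / 9, 4000 / 9, 1000 / 9, 2000 / 9), tolerance = 1e-12)
  expect_equal(round(rv2$edge_rc$rc, 1), c(222.2, 444.4, 111.1, 222.2))

  # single-target miRNA receives the full expression (conservation)
  solo <- star_network(3210, mirna_expr = 517)
  expect_equal(distribute_mirna(solo)$edge_rc$rc, 517)

  # all targets at zero: free miRNA, no sequestration
  zero <- star_network(c(0, 0))
  expect_message(rvz <- distribute_mirna(zero), "free")
  expect_equal(rvz$edge_rc$rc, c(0, 0))
  expect_equal(attr(rvz, "free_mirnas"), "M1")
})

test_that("gene repression aggregates region-weighted incoming counts", {
  # gene targeted by two miRNAs: plain sum when regions are neutral
  net <- build_network(
    data.frame(id = c("G1", "G2"), expression = c(100, 50)),
    data.frame(id = c("M1", "M2"), expression = c(286, 100)),
    data.frame(mirna = c("M1", "M2", "M2"), gene = c("G1", "G1", "G2"))
  )
  rv <- distribute_mirna(net)
  r <- gene_repression(rv, net)
  expect_equal(unname(r["G1"]), 286 + 100 * 100 / 150)

  # region effect scales degradation, not sequestration
  net2 <- build_network(
    data.frame(id = c("G1", "G2"), expression = c(100, 0)),
    data.frame(id = "M1", expression = 50),
    data.frame(mirna = c("M1", "M1"), gene = c("G1", "G2"),
               region_effect = c(0.5, 1))
  )
  rv2 <- distribute_mirna(net2)
  expect_equal(rv2$edge_rc$rc, c(50, 0))           # sequestration unweighted
  expect_equal(unname(gene_repression(rv2, net2)["G1"]), 25)  # degradation halved

  # untargeted genes get zero repression
  net3 <- build_network(
    data.frame(id = c("G1", "G2"), expression = c(100, 100)),
    data.frame(id = "M1", expression = 10),
    data.frame(mirna = "M1", gene = "G1")
  )
  expect_equal(unname(gene_repression(distribute_mirna(net3), net3)["G2"]), 0)
})

test_that("conservation, reduction, competition and scale covariance hold on random networks", {
  for (s in 1:25) {
    net <- random_cerna_network(n_genes = 12, n_mirnas = 4, edge_density = 0.4,
                                with_factors = (s %% 2 == 0), seed = s)
    rv <- distribute_mirna(net)
    totals <- tapply(rv$edge_rc$rc, rv$edge_rc$mirna, sum)
    mexpr <- setNames(net$mirnas$expression, net$mirnas$id)
    expect_equal(as.numeric(totals[names(mexpr)]), unname(mexpr),
                 tolerance = 1e-9)

    # scale covariance: scaling all gene expressions leaves RC unchanged
    scaled <- setNames(net$genes$expression * 7.3, net$genes$id)
    rv_s <- distribute_mirna(net, gene_expressions = scaled)
    expect_equal(rv_s$edge_rc$rc, rv$edge_rc$rc, tolerance = 1e-9)
  }

  # reduction: neutral factors reproduce the unweighted distribution edge-for-edge
  net_plain <- make_sample_network()
  suppressWarnings(net_neutral <- make_sample_plus_network(
    energies = rep(-10, 7), seed_effects = rep(1, 7),
    region_effects = rep(1, 7)))
  expect_equal(distribute_mirna(net_neutral)$edge_rc$rc,
               distribute_mirna(net_plain)$edge_rc$rc, tolerance = 1e-12)

  # with neutral regions, total repression equals the plain incoming sum
  rv <- distribute_mirna(net_plain)
  sums <- tapply(rv$edge_rc$rc, rv$edge_rc$gene, sum)
  r <- gene_repression(rv, net_plain)
  expect_equal(unname(r[names(sums)]), as.numeric(sums), tolerance = 1e-12)

  # monotone competition: raising one target strictly lowers RC on co-targets
  net <- star_network(c(10000, 10000, 5000, 10000))
  rv0 <- distribute_mirna(net)
  rv1 <- distribute_mirna(net, gene_expressions = c(G2 = 15000))
  expect_true(rv1$edge_rc$rc[2] > rv0$edge_rc$rc[2])
  expect_true(all(rv1$edge_rc$rc[-2] < rv0$edge_rc$rc[-2]))
})

test_that("distribution matches the exact fraction identity on small random networks", {
  # rational-arithmetic style oracle: cross-multiplication avoids any
  # floating-point division on the expected side
  for (s in 1:50) {
    set.seed(s)
    n_g <- sample(2:7, 1)
    n_m <- sample(1:3, 1)
    net <- suppressWarnings(random_cerna_network(
      n_genes = n_g, n_mirnas = n_m, edge_density = 0.7,
      with_factors = (s %% 3 == 0), seed = 1000 + s))
    # integer expressions keep the oracle arithmetic exact
    net$genes$expression <- round(net$genes$expression)
    net$mirnas$expression <- round(net$mirnas$expression)
    rv <- suppressMessages(distribute_mirna(net))
    expect_rc_matches_fraction(net, rv)
  }
})
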