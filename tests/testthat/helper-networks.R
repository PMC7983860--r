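# small networks used across test files

# one miRNA, k genes, explicit expressions
star_network <- function(gene_expr, mirna_expr = 1000, mirna_id = "M1") {
  k <- length(gene_expr)
  build_network(
    gene_expr = data.frame(id = paste0("G", seq_len(k)),
                           expression = gene_expr),
    mirna_expr = data.frame(id = mirna_id, expression = mirna_expr),
    edges = data.frame(mirna = mirna_id, gene = paste0("G", seq_len(k)))
  )
}

# worked-example network plus a disconnected star (M3 -> G7, G8)
two_component_network <- function() {
  build_network(
    gene_expr = data.frame(
      id = paste0("G", 1:8),
      expression = c(10000, 10000, 5000, 10000, 10000, 10000, 8000, 4000)
    ),
    mirna_expr = data.frame(id = c("M1", "M2", "M3"),
                            expression = c(1000, 1000, 500)),
    edges = data.frame(
      mirna = c("M1", "M1", "M1", "M1", "M2", "M2", "M2", "M3", "M3"),
      gene = c("G1", "G2", "G3", "G4", "G4", "G5", "G6", "G7", "G8")
    )
  )
}

# exact-rational check of the proportional-distribution fraction via
# cross-multiplication: rc * sum(w) must equal mirna_expr * w elementwise
expect_rc_matches_fraction <- function(network, rv) {
  ed <- network$edges
  gexpr <- setNames(network$genes$expression, network$genes$id)
  mexpr <- setNames(network$mirnas$expression, network$mirnas$id)
  w <- ed$affinity * gexpr[ed$gene]
  for (m in unique(ed$mirna)) {
    sel <- ed$mirna == m
    s <- sum(w[sel])
    lhs <- rv$edge_rc$rc[sel] * s
    rhs <- mexpr[m] * w[sel]
    expect_true(all(abs(lhs - rhs) <= 1e-9 * pmax(1, abs(rhs))),
                label = paste("cross-multiplied fraction identity for", m))
  }
}
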