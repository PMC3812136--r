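one_ffl <- function(cl = "TF_FFL", tf = "t1", m = "m1", g = "g1")
  data.frame(ffl_class = cl, tf_id = tf, mirna_id = m, target_gene_id = g,
             stringsAsFactors = FALSE)

test_that("network assembly unions motif edges with typed nodes", {
  net <- build_network(one_ffl())
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 3L)
  types <- setNames(igraph::V(net)$node_type, igraph::V(net)$name)
  expect_identical(types[["t1"]], "TF")
  expect_identical(types[["m1"]], "miRNA")
  expect_identical(types[["g1"]], "gene")
  # miRNA_regulation edges originate only from miRNA nodes
  ed <- igraph::as_data_frame(net)
  expect_true(all(ed$from[ed$regulation_type == "miRNA_regulation"] == "m1"))

  # a composite motif contributes 4 edges
  expect_equal(igraph::ecount(build_network(one_ffl("composite_FFL"))), 4L)

  # sharing a miRNA: node counted once, shared edge not duplicated
  two <- rbind(one_ffl(), one_ffl(tf = "t2", g = "g2"))
  net2 <- build_network(two)
  expect_equal(igraph::vcount(net2), 5L)
  expect_equal(igraph::ecount(net2), 6L)
  expect_equal(igraph::vcount(build_network(one_ffl()[0, ])), 0L)
})

test_that("edge count is bounded by 3 per simple motif and 4 per composite", {
  sim <- simulate_regulatory_data(sim_config(seed = 40))
  ffls <- sim$truth$planted_ffls
  net <- build_network(ffls)
  cnt <- count_ffls(ffls)
  expect_lte(igraph::ecount(net),
             3 * (cnt[["TF_FFL"]] + cnt[["miRNA_FFL"]]) +
               4 * cnt[["composite_FFL"]])
})

test_that("degree and hub follow the collapse-and-tie rules", {
  star <- do.call(rbind, lapply(1:5, function(i)
    one_ffl(tf = "c", m = paste0("m", i), g = paste0("g", i))))
  dh <- degree_and_hub(build_network(star))
  expect_equal(unname(dh$degree[["c"]]), 10L)  # 5 miRNAs + 5 genes
  expect_identical(dh$hub, "c")

  # tie between two equally connected regulators -> lexicographically first
  tie <- rbind(one_ffl(tf = "b", m = "zz", g = "g1"),
               one_ffl(tf = "a", m = "zz", g = "g1"))
  dh2 <- degree_and_hub(build_network(tie))
  expect_identical(dh2$hub, "g1")  # g1 and zz have degree 3; "g1" < "zz"
  expect_error(degree_and_hub(build_network(one_ffl()[0, ])), "empty")
})

test_that("a regulator joining many motifs becomes the hub", {
  set.seed(41)
  many <- do.call(rbind, lapply(1:40, function(i)
    one_ffl(tf = sprintf("t%02d", i), m = "hub-mir", g = sprintf("g%02d", i))))
  others <- do.call(rbind, lapply(1:20, function(i)
    one_ffl(tf = sprintf("t%02d", i), m = sprintf("m%02d", i),
            g = sprintf("h%02d", i))))
  dh <- degree_and_hub(build_network(rbind(many, others)))
  expect_identical(dh$hub, "hub-mir")
})

test_that("occurrence ranking orders by count with lexicographic tie order", {
  counts <- c(41, 19, 16, 16, 13)
  mirs <- c("mir-e", "mir-b", "mir-d", "mir-c", "mir-a")
  ffls <- do.call(rbind, lapply(seq_along(mirs), function(i)
    do.call(rbind, lapply(seq_len(counts[i]), function(j)
      one_ffl(tf = sprintf("t%d_%d", i, j), m = mirs[i],
              g = sprintf("g%d_%d", i, j))))))
  occ <- occurrence_ranking(list(prostate = ffls))
  mir_rows <- occ[occ$regulator_kind == "miRNA", ]
  expect_equal(mir_rows$prostate_ffls[match(mirs, mir_rows$id)], counts)
  # ranks 1..5 with the 16-tie broken lexicographically (mir-c before mir-d)
  expect_equal(mir_rows$prostate_rank[match(c("mir-e", "mir-b", "mir-c",
                                              "mir-d", "mir-a"), mir_rows$id)],
               1:5)
  # absent regulator is unranked with count 0 in the other dataset
  occ2 <- occurrence_ranking(list(a = ffls[1, ], b = ffls[50, ]))
  row <- occ2[occ2$id == ffls$mirna_id[1] & occ2$regulator_kind == "miRNA", ][1, ]
  expect_equal(row$b_ffls, 0L)
  expect_true(is.na(row$b_rank))
})

test_that("ego subnetwork keeps only centre-incident edges", {
  tri <- one_ffl("composite_FFL")  # t1<->m1 plus both -> g1
  net <- build_network(tri)
  ego_g <- ego_subnetwork(net, "g1")
  expect_setequal(igraph::V(ego_g)$name, c("t1", "m1", "g1"))
  ed <- igraph::as_data_frame(ego_g)
  expect_true(all(ed$from == "g1" | ed$to == "g1"))
  expect_equal(nrow(ed), 2L)

  # ego of the hub covers degree(hub) + 1 nodes
  star <- do.call(rbind, lapply(1:5, function(i)
    one_ffl(tf = "c", m = paste0("m", i), g = paste0("g", i))))
  snet <- build_network(star)
  dh <- degree_and_hub(snet)
  expect_equal(igraph::vcount(ego_subnetwork(snet, dh$hub)),
               unname(dh$degree[dh$hub]) + 1L)
  expect_error(ego_subnetwork(net, "nope"), "unknown node")
})

test_that("power-law fit recovers exact and degenerate exponents", {
  k <- c(1, 2, 4, 8, 16)  # powers of two keep count(k) = 256 k^-2 integral
  degrees <- rep(k, times = 256 / k^2)
  expect_equal(powerlaw_exponent(degrees), 2, tolerance = 1e-6)
  uniform <- rep(1:5, each = 10)
  expect_equal(powerlaw_exponent(uniform), 0, tolerance = 1e-9)
  expect_error(powerlaw_exponent(rep(c(1, 2), 5)), "distinct")

  set.seed(42)
  pa <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  expo <- powerlaw_exponent(igraph::degree(pa))
  expect_gt(expo, 1.5)
  expect_lt(expo, 3.5)
})

test_that("SIF and GraphML exports round-trip the typed structure", {
  net <- build_network(rbind(one_ffl(), one_ffl("miRNA_FFL", "t2", "m2", "g2")))
  sif <- tempfile(fileext = ".sif")
  export_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(net))
  expect_true(all(grepl("\t(TF|miRNA)_regulation\t", lines)))

  gml <- tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_setequal(igraph::V(back)$node_type, igraph::V(net)$node_type)
})
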