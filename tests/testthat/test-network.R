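test_that("assembly collapses referral multiplicity to binary ties", {
  roster <- make_nodes(6)
  rec <- data.frame(
    sender_id = c("F01", "F01", "F02", "F02", "F03"),
    receiver_id = c("F04", "F04", "F05", "F05", "F06"),
    condition_category = c("fever", "diarrhoea", "fever", "fever", "fever"),
    domain = "childcare", n_referrals = c(1L, 2L, 1L, 5L, 1L),
    stringsAsFactors = FALSE
  )
  net <- assemble_network(rec, roster, "testland", "childcare")
  expect_equal(network_edge_count(net), 3)
  expect_equal(net$adjacency["F01", "F04"], 1L)

  ## zero matching records: all nodes isolates
  net2 <- assemble_network(rec, roster, "testland", "ncd")
  expect_equal(network_edge_count(net2), 0)
  expect_equal(network_size(net2), 6)
})

test_that("assembled edge count equals distinct ordered sender-receiver pairs", {
  roster <- make_nodes(10)
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(1:25, 1)
    s <- sample(roster$facility_id, k, replace = TRUE)
    r <- sample(roster$facility_id, k, replace = TRUE)
    keep <- s != r
    rec <- data.frame(sender_id = s[keep], receiver_id = r[keep],
                      condition_category = "c", domain = "ncd",
                      n_referrals = 1L, stringsAsFactors = FALSE)
    if (nrow(rec) == 0) next
    net <- assemble_network(rec, roster, "testland", "ncd")
    expect_equal(network_edge_count(net),
                 nrow(unique(rec[c("sender_id", "receiver_id")])))
    ## order independence
    net2 <- assemble_network(rec[rev(seq_len(nrow(rec))), ], roster,
                             "testland", "ncd")
    expect_identical(net$adjacency, net2$adjacency)
  }
})

test_that("external referral destinations join the sender's district network", {
  roster <- rbind(make_nodes(5), make_nodes(3))
  roster$facility_id <- sprintf("F%02d", 1:8)
  roster$district[6:8] <- "elsewhere"
  rec <- data.frame(sender_id = c("F01", "F02"),
                    receiver_id = c("F06", "F03"),
                    condition_category = "c", domain = "childcare",
                    n_referrals = 1L, stringsAsFactors = FALSE)
  net <- assemble_network(rec, roster, "testland", "childcare")
  expect_equal(network_size(net), 6)   # 5 in-district + 1 external receiver
  expect_true("F06" %in% net$nodes$facility_id)
  expect_false("F07" %in% net$nodes$facility_id)
  ## a record for an unknown facility is a hard error
  bad <- rbind(rec, data.frame(sender_id = "F01", receiver_id = "NOPE",
                               condition_category = "c", domain = "childcare",
                               n_referrals = 1L))
  expect_error(assemble_network(bad, roster, "testland", "childcare"),
               class = "referralnet_data_error")
})

test_that("category filter subsets records and the union reproduces the whole", {
  roster <- make_nodes(8)
  set.seed(4)
  rec <- data.frame(
    sender_id = sprintf("F%02d", sample(1:4, 12, TRUE)),
    receiver_id = sprintf("F%02d", sample(5:8, 12, TRUE)),
    condition_category = sample(c("a", "b", "c"), 12, TRUE),
    domain = "childcare", n_referrals = 1L, stringsAsFactors = FALSE
  )
  one <- filter_by_category(rec, "a")
  expect_true(all(one$condition_category == "a"))
  expect_warning(none <- filter_by_category(rec, "zz"), "zz")
  expect_equal(nrow(none), 0)

  full <- assemble_network(rec, roster, "testland", "childcare")
  y_union <- matrix(0L, network_size(full), network_size(full))
  for (cat in c("a", "b", "c")) {
    sub <- filter_by_category(rec, cat)
    if (nrow(sub) == 0) next
    net_c <- assemble_network(sub, roster, "testland", "childcare")
    idx <- match(net_c$nodes$facility_id, full$nodes$facility_id)
    y_union[idx, idx] <- pmax(y_union[idx, idx], net_c$adjacency)
  }
  expect_equal(y_union, unname(full$adjacency))
})

test_that("self-ties and non-binary adjacency are rejected", {
  y <- matrix(0L, 3, 3); y[1, 1] <- 1L
  expect_error(make_net(y), "self-ties", class = "referralnet_data_error")
  y2 <- matrix(0L, 3, 3); y2[1, 2] <- 2L
  expect_error(make_net(y2), class = "referralnet_data_error")
})
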