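test_that("encoder produces posterior parameters of the right shape", {
  g <- random_toy_graph(8, 0.4, seed = 1)
  X <- matrix(rnorm(8 * 10), 8, 10)
  model <- vgae_init(10, hidden_dims = c(6, 5), latent_dim = 3, n_heads = 2,
                     seed = 2)
  enc <- vgae_encode(model, X, g)
  expect_equal(dim(enc$mu), c(8, 3))
  expect_equal(dim(enc$log_sigma), c(8, 3))
  # attention recorded for 2 inner + 2 output layers
  expect_setequal(unique(enc$attention$layer), 1:4)
  expect_error(vgae_encode(model, matrix(0, 8, 9), g), "width")
})

test_that("a one-inner-layer encoder composes exactly from layer primitives", {
  g <- random_toy_graph(6, 0.5, seed = 4)
  X <- matrix(rnorm(6 * 5), 6, 5)
  model <- vgae_init(5, hidden_dims = 4, latent_dim = 2, n_heads = 1, seed = 9)
  enc <- vgae_encode(model, X, g)
  h1 <- gat_forward(X, model$inner[[1]], g)$output
  mu <- gat_forward(pmax(h1, 0), model$mu_layer, g)$output
  ls <- gat_forward(pmax(h1, 0), model$sigma_layer, g)$output
  expect_equal(enc$mu, mu, tolerance = 1e-12)
  expect_equal(enc$log_sigma, ls, tolerance = 1e-12)
})

test_that("zero input features yield zero posterior parameters", {
  g <- cell_graph(4, rbind(c(1, 2), c(3, 4)))
  model <- vgae_init(3, hidden_dims = 4, latent_dim = 2, n_heads = 2, seed = 1)
  enc <- vgae_encode(model, matrix(0, 4, 3), g)
  expect_equal(enc$mu, matrix(0, 4, 2))
  expect_equal(enc$log_sigma, matrix(0, 4, 2))
})

test_that("reparameterization is seeded, deterministic and unbiased", {
  enc <- list(mu = matrix(5, 100, 1), log_sigma = matrix(0, 100, 1))
  expect_equal(reparameterize(enc, epsilon = matrix(0, 100, 1))$Z, enc$mu)

  tiny <- list(mu = matrix(2, 3, 2), log_sigma = matrix(-20, 3, 2))
  expect_equal(reparameterize(tiny, seed = 1)$Z, tiny$mu, tolerance = 1e-6)

  expect_identical(reparameterize(enc, seed = 7)$Z,
                   reparameterize(enc, seed = 7)$Z)

  # Monte-Carlo check of the stated distribution: mean of mu + sigma*eps
  big <- list(mu = matrix(5, 1e5, 1), log_sigma = matrix(0, 1e5, 1))
  z <- reparameterize(big, seed = 11)$Z
  expect_lt(abs(mean(z) - 5), 0.02)
})

test_that("inner-product decoder follows the logistic sigmoid", {
  expect_equal(decode_edge_prob(c(0, 0), c(0, 0)), 0.5)
  expect_equal(decode_edge_prob(2, 2), plogis(4), tolerance = 1e-12)
  expect_equal(decode_edge_prob(2, 2), 0.9820, tolerance = 1e-4)
  set.seed(3)
  for (i in 1:5) {
    zi <- rnorm(4); zj <- rnorm(4)
    expect_equal(decode_edge_prob(zi, zj), decode_edge_prob(zj, zi))
  }
  expect_error(decode_edge_prob(c(1, 2), 1), "length")
})

test_that("KL loss matches its closed form and vanishes only at the prior", {
  expect_equal(kl_loss(list(mu = matrix(0, 2, 3), log_sigma = matrix(0, 2, 3))), 0)
  expect_equal(kl_loss(list(mu = matrix(1), log_sigma = matrix(0))), 0.5)
  # mu = 0, sigma^2 = e: 0.5 * (e - 1 - 1)
  expect_equal(kl_loss(list(mu = matrix(0), log_sigma = matrix(0.5))),
               0.5 * (exp(1) - 2), tolerance = 1e-12)
  expect_equal(round(kl_loss(list(mu = matrix(0), log_sigma = matrix(0.5))), 4),
               0.3591)
  set.seed(1)
  off <- list(mu = matrix(rnorm(6), 2, 3), log_sigma = matrix(rnorm(6), 2, 3))
  expect_gt(kl_loss(off), 0)
})

test_that("MMD is zero on identical samples, non-negative, and exact on singletons", {
  set.seed(5)
  Z <- matrix(rnorm(40), 10, 4)
  expect_equal(mmd_loss(Z, Z), 0, tolerance = 1e-12)
  P <- matrix(rnorm(40), 10, 4)
  expect_gte(mmd_loss(Z, P), 0)
  # two singleton sets: 2 - 2 * exp(-||z - z2||^2 / (2 bw))
  z1 <- matrix(c(1, 2), 1, 2); z2 <- matrix(c(0, 0), 1, 2)
  bw <- 3
  expect_equal(mmd_loss(z1, z2, bandwidth = bw),
               2 - 2 * exp(-5 / (2 * bw)), tolerance = 1e-12)
  expect_error(mmd_loss(Z[0, , drop = FALSE], P), "non-empty")
})

test_that("edge reconstruction loss matches closed forms and is monotone", {
  # one positive + one negative, both predicted at 0.5 -> log 2
  Z <- matrix(0, 3, 2)
  pos <- rbind(c(1L, 2L)); neg <- rbind(c(1L, 3L))
  expect_equal(recon_loss(Z, pos, neg), log(2), tolerance = 1e-12)

  # single positive with decoded probability e^-1 -> loss exactly 1
  a <- 1; b <- qlogis(exp(-1))
  Z2 <- matrix(c(a, b, 0, 0), 2, 2)
  expect_equal(recon_loss(Z2, rbind(c(1L, 2L))), 1, tolerance = 1e-10)

  # perfect predictions drive the loss toward 0 (and clamping keeps it finite)
  Zp <- matrix(c(10, 10, -10), 3, 1)
  expect_lt(recon_loss(Zp, rbind(c(1L, 2L)), rbind(c(1L, 3L))), 1e-6)

  # elementwise monotonicity: better scores, lower loss
  s <- seq(0.2, 3, length.out = 8)
  losses <- vapply(s, function(scale) {
    Zs <- matrix(c(scale, scale, -scale), 3, 1)
    recon_loss(Zs, rbind(c(1L, 2L)), rbind(c(1L, 3L)))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(recon_loss(Z, matrix(integer(), ncol = 2)), "non-empty")
})

test_that("feature reconstruction MSE behaves as mean squared error", {
  Z <- matrix(rnorm(6), 3, 2)
  net <- list(W = matrix(rnorm(8), 4, 2), b = rep(0, 4))
  X <- sweep(Z %*% t(net$W), 2, net$b, "+")
  expect_equal(feature_recon_loss(Z, X, net), 0, tolerance = 1e-12)
  zeronet <- list(W = matrix(0, 4, 2), b = rep(0, 4))
  expect_equal(feature_recon_loss(Z, matrix(1, 3, 4), zeronet), 1)
  halfnet <- list(W = matrix(0, 1, 1), b = 0.5)
  expect_equal(feature_recon_loss(matrix(0), matrix(1), halfnet), 0.25)
})

test_that("total loss is additive in its components", {
  expect_equal(total_loss(list(reg = 0, recon = 0)), 0)
  expect_equal(total_loss(list(reg = 0.5, recon = log(2))), 0.5 + log(2))
  comp <- list(reg = 0.2, recon = 0.3, feature_recon = 0.4)
  expect_equal(total_loss(comp, use_feature_recon = TRUE) -
                 total_loss(comp), 0.4, tolerance = 1e-12)
  expect_error(total_loss(list(reg = 1, recon = 1), reg_kind = "bogus"))
})

test_that("analytic gradients match finite differences on a toy model", {
  g <- cell_graph(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                           c(1, 6), c(2, 5)))
  set.seed(42)
  X <- matrix(rnorm(24), 6, 4)
  model <- vgae_init(4, hidden_dims = 3, latent_dim = 2, n_heads = 2,
                     use_feature_recon = TRUE, seed = 7)
  pos <- g$edges
  neg <- sample_negative_edges(g, nrow(pos), seed = 3)
  eps <- matrix(rnorm(12), 6, 2)
  prior <- matrix(rnorm(12), 6, 2)

  for (kind in c("kl", "mmd")) {
    f <- function(m) {
      scvgae:::vgae_loss_and_grads(m, X, g, pos, neg, eps, reg_kind = kind,
                                   prior_samples = prior,
                                   use_feature_recon = TRUE)
    }
    res <- f(model)
    params <- scvgae:::model_params(model)
    h <- 1e-5
    check_block <- function(getter, setter, analytic) {
      p <- getter(params)
      idx <- seq_along(p)
      if (length(idx) > 6) idx <- idx[c(1, 2, length(idx))]  # spot checks
      for (i in idx) {
        up <- p; up[i] <- up[i] + h
        dn <- p; dn[i] <- dn[i] - h
        l1 <- f(scvgae:::set_model_params(model, setter(params, up)))$loss
        l2 <- f(scvgae:::set_model_params(model, setter(params, dn)))$loss
        expect_equal((l1 - l2) / (2 * h), analytic[i], tolerance = 1e-4)
      }
    }
    check_block(function(p) p$inner[[1]][[1]]$W,
                function(p, v) { p$inner[[1]][[1]]$W <- matrix(v, 3); p },
                res$grads$inner[[1]][[1]]$W)
    check_block(function(p) p$inner[[1]][[2]]$a_src,
                function(p, v) { p$inner[[1]][[2]]$a_src <- v; p },
                res$grads$inner[[1]][[2]]$a_src)
    check_block(function(p) p$mu[[1]]$W,
                function(p, v) { p$mu[[1]]$W <- matrix(v, 2); p },
                res$grads$mu[[1]]$W)
    check_block(function(p) p$sigma[[2]]$a_dst,
                function(p, v) { p$sigma[[2]]$a_dst <- v; p },
                res$grads$sigma[[2]]$a_dst)
    check_block(function(p) p$recon$W,
                function(p, v) { p$recon$W <- matrix(v, 4); p },
                res$grads$recon$W)
  }
})
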