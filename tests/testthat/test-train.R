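# Training loop mechanics on miniature problems: schedule, determinism,
# evaluation harness, checkpoint reproducibility, ablation table structure.

tiny_setup <- function(n = 3, seed = 41) {
  spec <- phantom_spec(shape = c(6L, 32L, 32L), liver_radius = c(8, 11),
                       tumor_radius = c(2.5, 4), tumor_z_radius = c(1, 1.5),
                       liver_z_radius = c(1.5, 2.5), n_tumors = c(1L, 1L))
  prepare_volumes(generate_phantom_dataset(n, spec, seed = seed))
}

tiny_cfg <- function(epochs = 1, seed = 1) {
  train_config(batch_size = 2, epochs = epochs, crop_size = 32, seed = seed)
}

tiny_net <- function(seed = 42) {
  rheu_net(network_config(base_width = 2, depth = 2, dropout_rate = 0.1,
                          seed = seed))
}

test_that("the learning rate decays exponentially from 1e-4 at rate 0.95", {
  cfg <- train_config()
  expect_identical(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(1, cfg), 9.5e-5)
  e <- 0:20
  expect_equal(lr_schedule(e + 1, cfg) / lr_schedule(e, cfg), rep(0.95, 21))
  expect_equal(lr_schedule(120, cfg), 1e-4 * 0.95^120)   # about 2.13e-7
  expect_error(lr_schedule(-1, cfg))
})

test_that("training runs, logs epochs from zero, and is seed-deterministic", {
  vols <- tiny_setup()
  f1 <- suppressWarnings(train_model(tiny_net(), vols[1:2], tiny_cfg(epochs = 2),
                                     vols[3]))
  expect_equal(f1$log$epoch, c(0, 1))
  expect_true(all(is.finite(f1$log$train_loss)))
  expect_true(all(diff(f1$log$lr) < 0))

  f2 <- suppressWarnings(train_model(tiny_net(), vols[1:2], tiny_cfg(epochs = 2),
                                     vols[3]))
  expect_identical(f1$log$train_loss[1], f2$log$train_loss[1])
  expect_identical(f1$log$val_loss, f2$log$val_loss)

  f3 <- suppressWarnings(train_model(tiny_net(), vols[1:2],
                                     tiny_cfg(epochs = 1, seed = 9), vols[3]))
  expect_false(identical(f1$log$train_loss[1], f3$log$train_loss[1]))

  expect_error(train_model(tiny_net(), list(), tiny_cfg()), "empty")
})

test_that("the best validation checkpoint is restored into the returned model", {
  vols <- tiny_setup(n = 3, seed = 51)
  fit <- suppressWarnings(train_model(tiny_net(), vols[1:2], tiny_cfg(epochs = 3),
                                      vols[3]))
  expect_true(fit$best_epoch %in% fit$log$epoch)
  best_mean <- mean(c(fit$log$val_dice_liver, fit$log$val_dice_tumor)[
    c(fit$best_epoch + 1, nrow(fit$log) + fit$best_epoch + 1)])
  expect_gte(best_mean,
             mean(c(fit$log$val_dice_liver[1], fit$log$val_dice_tumor[1])) - 1e-12)
})

test_that("evaluation of an untrained model yields a well-formed percentage report", {
  vols <- tiny_setup(n = 2, seed = 61)
  net <- tiny_net()
  suppressWarnings(rep <- evaluate_model(net, vols))
  expect_s3_class(rep, "metric_report")
  expect_identical(rep$per_class$class, c("liver", "tumor"))
  expect_true(all(rep$per_class$dice >= 0 & rep$per_class$dice <= 100))
  expect_identical(rep$n_cases, 2L)
  expect_error(evaluate_model(net, list()), "empty")
})

test_that("checkpoint round trips reproduce the evaluation report bitwise", {
  vols <- tiny_setup(n = 2, seed = 71)
  net <- tiny_net()
  suppressWarnings(r1 <- evaluate_model(net, vols))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)$network
  suppressWarnings(r2 <- evaluate_model(net2, vols))
  expect_identical(r1$per_class, r2$per_class)
})

test_that("the ablation grid produces the six-model four-metric table", {
  vols <- tiny_setup(n = 4, seed = 81)
  tab <- suppressWarnings(
    run_ablation(vols[1:2], vols[3], vols[4], tiny_cfg(epochs = 1),
                 base_width = 2, depth = 2, net_seed = 5)
  )
  expect_identical(nrow(tab), 12L)   # 6 models x 2 classes
  expect_identical(unique(tab$model),
                   c("U-Net", "Res+U-Net", "HGA+U-Net", "MSFE+U-Net",
                     "Res+HGA+U-Net", "RHEU-Net"))
  expect_true(all(tab$dice >= 0 & tab$dice <= 100))
  expect_true(all(c("jaccard", "precision", "recall") %in% names(tab)))
})
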