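# Shared end-to-end fixture: one seeded desk-scale run of the full pipeline
# (synthetic 7-class data at 32 x 64, 40 maps/class for training, a 10/class
# holdout; CNN classifier; CAG adversarial training; evaluation protocols).
# Built lazily once per test session and reused by every block that needs a
# trained system.

e2e_env <- new.env(parent = emptyenv())

e2e_fixture <- function() {
  if (!is.null(e2e_env$fix)) return(e2e_env$fix)
  seed <- 101L
  full <- generate_synthetic_dataset(synth_config(n_per_class = 50L, seed = seed))
  sp <- split_dataset(full, 10L, seed = seed + 1L)
  train <- sp$train
  holdout <- sp$holdout

  ccfg <- classifier_config(K = 7L, lr = 0.05, epochs = 20L, folds = 0L,
                            seed = seed + 2L)
  clf <- train_classifier(build_classifier(ccfg, c(32L, 64L)), train,
                          ccfg)$classifier
  pred <- predict(clf, holdout)$class
  labs <- cagen:::ds_labels(holdout)

  tcfg <- cag_train_config(batch_size = 16L, lr = 2e-4, gen_steps = 250L,
                           seed = seed + 3L)
  cag <- train_cag(clf, train, loss_weights(), tcfg)

  res_correct <- explain_correct(cag$gen, clf, holdout, seed = seed + 4L)
  res_incorrect <- if (any(pred != labs))
    explain_misclassification(cag$gen, clf, holdout) else NULL

  battery <- feature_battery(cag$gen, clf, holdout, n_features = 12L,
                             seed = seed + 5L)

  e2e_env$fix <- list(train = train, holdout = holdout, clf = clf,
                      gen = cag$gen, disc = cag$disc, history = cag$history,
                      pred = pred, labs = labs, acc = mean(pred == labs),
                      res_correct = res_correct,
                      res_incorrect = res_incorrect, battery = battery)
  e2e_env$fix
}
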