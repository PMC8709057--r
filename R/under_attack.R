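# Combined evaluation: the classifier behind the integrity scheme.

# One receiver-side pass of a dataset through the BHR: legitimate trials
# are encoded under the defender's synchronized tuple, fake trials are
# forged under an independent attacker guess; returns which trials were
# forced to nonP300 and the features of the reconstructed survivors.
bhr_pass <- function(dataset, bhr_cfg = bhr_config(),
                     prep_cfg = prep_config(), seed = 1L) {
  trials <- dataset$trials
  n <- length(trials)
  prng <- bhr_prng(seed)
  forced <- logical(n)
  kept <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    tuple <- next_tuple(prng, bhr_cfg$n_channels)
    frame <- soft_clip(tr$data, bhr_cfg$amplitude_bound)
    mixed <- if (tr$provenance == "fake") {
      guess <- with_seed(mix_seed(seed, 7000000L + i),
                         sample.int(bhr_cfg$n_channels, 4L))
      bhr_forge(frame, guess, bhr_cfg)
    } else {
      bhr_encode(frame, tuple, bhr_cfg)
    }
    res <- bhr_decode_verify(mixed, tuple, bhr_cfg)
    if (res$verdict == "compromised") {
      forced[i] <- TRUE
    } else {
      rec <- tr
      rec$data <- res$frame
      kept[[i]] <- rec
    }
  }
  pass <- which(!forced)
  features <- if (length(pass)) {
    extract_features_batch(kept[pass], prep_cfg)$features
  }
  list(forced = forced, pass = pass, features = features,
       labels = vapply(trials, `[[`, "", "label"))
}

bhr_metrics <- function(model, pass_obj) {
  n <- length(pass_obj$labels)
  pred <- rep("nonP300", n)
  if (length(pass_obj$pass)) {
    pred[pass_obj$pass] <- predict(model, pass_obj$features)
  }
  rep <- metrics_from_predictions(pred, pass_obj$labels)
  attr(rep, "warnings") <- sum(pass_obj$forced)
  rep
}

#' Evaluate a classifier on an (optionally hacked) dataset, with or
#' without the integrity scheme
#'
#' Without the BHR, every trial is preprocessed and classified directly.
#' With the BHR enabled, every trial travels the encode -> verify path:
#' legitimate (real/synthetic) trials are encoded under the defender's
#' synchronized tuple, while fake trials are forged by the attacker under
#' an independent uniform tuple guess. Frames failing verification are
#' forced to `"nonP300"` by the inhibition policy; frames passing are
#' reconstructed (channel d policy-filled) and classified normally.
#'
#' @param model a [train_svm()] model.
#' @param dataset a `subject_dataset` or [inject()] `hacked_dataset`.
#' @param bhr_enabled logical; route trials through the BHR.
#' @param bhr_cfg a [bhr_config()].
#' @param prep_cfg the [prep_config()] used when training the model.
#' @param seed seed of the defender generator and the attacker guesses.
#' @return a [metrics_report]; attribute `warnings` counts BHR alerts.
#' @export
evaluate_under_attack <- function(model, dataset, bhr_enabled = FALSE,
                                  bhr_cfg = bhr_config(),
                                  prep_cfg = prep_config(), seed = 1L) {
  stopifnot(inherits(model, "p300_svm"))
  if (!bhr_enabled) {
    fb <- extract_features_batch(dataset, prep_cfg)
    rep <- metrics_from_predictions(predict(model, fb$features), fb$labels)
    attr(rep, "warnings") <- 0L
    return(rep)
  }
  bhr_metrics(model, bhr_pass(dataset, bhr_cfg, prep_cfg, seed))
}

#' Attack-impact experiment over kernels, presets and seeds
#'
#' Emulates the per-subject evaluation protocol: for each seed, a victim
#' subject contributes an independent training and testing set (same
#' morphology, fresh noise); the five kernel classifiers are trained on
#' the training set and evaluated on the clean testing set, on its hacked
#' variants, and (optionally) on each of those behind the BHR. The
#' attacker's forgery templates are built from a different donor subject
#' ([subject_profile_variant()]), matching the threat model in which the
#' victim's own recordings are unavailable to the attacker. One BHR decode
#' pass per dataset is shared by all kernels. The direction-of-effect
#' contrasts (does every attack reduce mean precision? does the BHR trade
#' recall for precision?) are computed from the returned table.
#'
#' @param seeds integer vector of experiment seeds.
#' @param scale dataset scale passed to [synth_dataset()] (1 = 240 + 1200
#'   trials per subject).
#' @param kernels kernel kinds to train.
#' @param presets attack preset names (see [attack_presets()]).
#' @param bhr also evaluate behind the integrity scheme.
#' @param prep_cfg a [prep_config()].
#' @param progress print one line per seed.
#' @return data frame with columns `seed`, `kernel`, `dataset`
#'   (`"clean"` or a preset name), `bhr`, `A`, `PPV`, `TPR`, `F1`,
#'   `warnings`.
#' @export
attack_impact_experiment <- function(seeds = 1:5, scale = 1,
                                     kernels = c("L", "Q", "C", "MG", "CG"),
                                     presets = names(attack_presets()),
                                     bhr = TRUE,
                                     prep_cfg = prep_config(),
                                     progress = FALSE) {
  rows <- list()
  add <- function(seed, kernel, dataset, bhr_on, rep) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seed = seed, kernel = kernel, dataset = dataset, bhr = bhr_on,
      A = rep$A, PPV = rep$PPV, TPR = rep$TPR, F1 = rep$F1,
      warnings = attr(rep, "warnings") %||% 0L)
  }
  n_p3 <- round(240 * scale)
  n_np <- round(1200 * scale)
  for (seed in seeds) {
    victim <- subject_profile_variant(1L, seed = seed, subject_id = "victim")
    donor <- subject_profile_variant(2L, seed = seed, subject_id = "donor")
    train_ds <- synth_subject(victim, n_p3, n_np, seed = mix_seed(seed, 1L))
    test_ds <- synth_subject(victim, n_p3, n_np, seed = mix_seed(seed, 2L))
    donor_ds <- synth_subject(donor, n_p3, n_np, seed = mix_seed(seed, 3L))
    fb_tr <- extract_features_batch(train_ds, prep_cfg)
    fits <- lapply(kernels, function(k)
      train_svm(fb_tr$features, fb_tr$labels, k, k_folds = 0, seed = seed))
    names(fits) <- kernels
    tmpl <- build_templates(donor_ds, filter_order = 9L)
    sets <- c(list(clean = test_ds),
              stats::setNames(lapply(presets, function(p)
                inject(test_ds, p, templates = tmpl,
                       attack_seed = mix_seed(seed, 55L))), presets))
    for (nm in names(sets)) {
      fb <- extract_features_batch(sets[[nm]], prep_cfg)
      for (k in kernels) {
        rp <- metrics_from_predictions(predict(fits[[k]], fb$features),
                                       fb$labels)
        attr(rp, "warnings") <- 0L
        add(seed, k, nm, FALSE, rp)
      }
      if (bhr) {
        po <- bhr_pass(sets[[nm]], prep_cfg = prep_cfg,
                       seed = mix_seed(seed, 77L))
        for (k in kernels) add(seed, k, nm, TRUE, bhr_metrics(fits[[k]], po))
      }
    }
    if (progress) message(sprintf("seed %d done", seed))
  }
  do.call(rbind, rows)
}
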