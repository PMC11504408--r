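# Training / evaluation orchestration: folder datasets, the Adam recipe
# (lr 0.001, 256x256 inputs, batch 32, 200 epochs by default), loss and
# metric logging, checkpointing, and the ablation grid.

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam, initial learning rate
#' 0.001, 256x256 inputs, batch size 32, 200 epochs.  No learning-rate
#' schedule is applied (only the initial rate is specified); a schedule
#' hook is exposed via `lr_schedule`.
#'
#' @param learning_rate Adam learning rate.
#' @param input_side Image side fed to the network.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param seed RNG seed controlling shuffling, augmentation and weight
#'   initialization downstream.
#' @param augment Apply the paired augmentations during training.
#' @param val_frac Fraction of the dataset held out (seed-stable
#'   shuffle) for validation-based checkpoint selection; 0 disables.
#' @param lr_schedule Optional `function(epoch, lr0)` returning the rate
#'   for that epoch.
#' @param early_stop_dsc Optional train-set Dice threshold; training
#'   stops once reached (checked every `check_every` epochs).
#' @param check_every Interval (epochs) for Dice checks/logging.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, input_side = 256L,
                         batch_size = 32L, epochs = 200L, seed = 1L,
                         augment = TRUE, val_frac = 0, lr_schedule = NULL,
                         early_stop_dsc = NULL, check_every = 10L) {
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 input_side = as.integer(input_side),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment = isTRUE(augment), val_frac = val_frac,
                 lr_schedule = lr_schedule, early_stop_dsc = early_stop_dsc,
                 check_every = as.integer(check_every)),
            class = "train_config")
}

#' Load an image/mask folder dataset
#'
#' Expects `images/` and `masks/` subfolders with name-matched PNG
#' files.  Images are rescaled to \[0, 1\] and bilinearly resized to
#' `input_side`; masks are nearest-neighbor resized and binarized at
#' 128/255.
#'
#' @param root Dataset directory.
#' @param input_side Target side in pixels.
#' @return A `seg_dataset`: list of `list(id, image, mask)` entries.
#' @export
load_dataset <- function(root, input_side = 256L) {
  imgdir <- file.path(root, "images")
  mskdir <- file.path(root, "masks")
  if (!dir.exists(imgdir) || !dir.exists(mskdir))
    stop("expected images/ and masks/ under ", root)
  imgs <- sort(list.files(imgdir, pattern = "\\.png$"))
  msks <- sort(list.files(mskdir, pattern = "\\.png$"))
  missing_m <- setdiff(imgs, msks)
  missing_i <- setdiff(msks, imgs)
  if (length(missing_m) || length(missing_i))
    stop("unmatched files - images without masks: [",
         paste(missing_m, collapse = ", "), "]; masks without images: [",
         paste(missing_i, collapse = ", "), "]")
  if (length(imgs) == 0L) stop("empty dataset at ", root)
  items <- lapply(imgs, function(f) {
    im <- resize_matrix(read_gray_png(file.path(imgdir, f)), input_side, "bilinear")
    mk <- resize_matrix(read_gray_png(file.path(mskdir, f)), input_side, "nearest")
    list(id = tools::file_path_sans_ext(f), image = im,
         mask = (mk >= 128 / 255) + 0)
  })
  structure(items, class = "seg_dataset")
}

dataset_batch <- function(dataset, idx, augment_seeds = NULL) {
  b <- length(idx)
  side <- nrow(dataset[[idx[1]]]$image)
  x <- array(0, c(b, 1L, side, side))
  g <- array(0, c(b, 1L, side, side))
  for (k in seq_len(b)) {
    it <- dataset[[idx[k]]]
    im <- it$image; mk <- it$mask
    if (!is.null(augment_seeds)) {
      au <- augment(im, mk, augment_seeds[k])
      im <- au$image; mk <- au$mask
    }
    x[k, 1L, , ] <- im
    g[k, 1L, , ] <- mk
  }
  list(x = x, g = g)
}

train_dsc <- function(model, dataset, idx, threshold = 0.5) {
  batch <- dataset_batch(dataset, idx)
  p <- mrdb_forward(batch$x, model, training = FALSE)
  mean(vapply(seq_along(idx), function(k)
    dsc(p[k, 1, , ] >= threshold, batch$g[k, 1, , ] > 0), numeric(1)))
}

#' Train an MRDB model
#'
#' Runs Adam on the hybrid Dice + BCE + 0.5 Smooth L1 loss.  With
#' `cfg$val_frac > 0` the dataset is split
#' by a seed-stable shuffle and the weights with the best validation
#' Dice are restored at the end; otherwise the final weights are kept.
#'
#' @param model An `mrdb_model` from [mrdb_init()].
#' @param dataset A `seg_dataset` (image sides must match the model).
#' @param cfg A [train_config()].
#' @param checkpoint Optional path; the trained model is saved there.
#' @param log_csv Optional path for the per-epoch loss/metric log.
#' @param verbose Print progress lines.
#' @return List with `model`, `log` (data.frame epoch/loss/dsc) and
#'   `checkpoint` path (or NULL).
#' @export
train_mrdb <- function(model, dataset, cfg = train_config(), checkpoint = NULL,
                       log_csv = NULL, verbose = FALSE) {
  stopifnot(length(dataset) > 0L)
  set.seed(cfg$seed)
  n <- length(dataset)
  perm <- sample.int(n)
  n_val <- floor(cfg$val_frac * n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  params <- ag_params(unclass(model))
  opt <- adam_new(params, lr = cfg$learning_rate)
  log <- data.frame(epoch = integer(0), loss = numeric(0), dsc = numeric(0))
  best <- list(dsc = -Inf, weights = NULL)
  aug_counter <- 0L
  for (ep in seq_len(cfg$epochs)) {
    if (!is.null(cfg$lr_schedule)) opt$lr <- cfg$lr_schedule(ep, cfg$learning_rate)
    order_ep <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(order_ep), by = cfg$batch_size)) {
      idx <- order_ep[start:min(start + cfg$batch_size - 1L, length(order_ep))]
      aseeds <- if (cfg$augment) cfg$seed * 1000L + aug_counter + seq_along(idx) else NULL
      aug_counter <- aug_counter + length(idx)
      batch <- dataset_batch(dataset, idx, aseeds)
      ag_tape_begin()
      pred <- ag_mrdb(model, ag_const(batch$x), list(training = TRUE))
      loss <- ag_hybrid(pred, batch$g)
      if (!is.finite(loss$value))
        stop("training diverged: non-finite loss at epoch ", ep)
      ag_zero_grads(params)
      ag_backward(loss)
      ag_tape_end()
      opt <- adam_step(opt)
      ep_loss <- ep_loss + loss$value; nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    d <- NA_real_
    if (ep %% cfg$check_every == 0L || ep == cfg$epochs) {
      d <- train_dsc(model, dataset, if (n_val > 0) val_idx else tr_idx)
      if (n_val > 0 && d > best$dsc)
        best <- list(dsc = d, weights = weights_pack(unclass(model)))
      if (verbose) message(sprintf("epoch %d  loss %.4f  dsc %.4f", ep, ep_loss, d))
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss, dsc = d))
    if (!is.null(cfg$early_stop_dsc) && is.finite(d) && d >= cfg$early_stop_dsc) break
  }
  if (n_val > 0 && !is.null(best$weights))
    weights_unpack(unclass(model), best$weights)
  if (!is.null(log_csv)) utils::write.csv(log, log_csv, row.names = FALSE)
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model, log = log, checkpoint = checkpoint)
}

#' Evaluate a model on a dataset
#'
#' Computes per-image Dice, Jaccard, sensitivity, HD95 and FNR at the
#' given threshold plus the pooled precision-recall AUC, optionally
#' writing the fixed-column CSV report (one row per image plus a mean
#' summary row).  The evaluation path is deterministic: the same
#' checkpoint and data produce byte-identical CSVs.
#'
#' @param model An `mrdb_model` (or a checkpoint path).
#' @param dataset A `seg_dataset` whose image side matches the model.
#' @param out_csv Optional CSV path.
#' @param threshold Binarization threshold (default 0.5).
#' @return List with `per_image` (data.frame), `summary` (means + pooled
#'   `pr_auc`).
#' @export
evaluate_mrdb <- function(model, dataset, out_csv = NULL, threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  side <- model$config$input_side
  if (nrow(dataset[[1]]$image) != side)
    stop("dataset side ", nrow(dataset[[1]]$image),
         " does not match model input_side ", side)
  rows <- list(); scores <- list(); gts <- list()
  for (i in seq_along(dataset)) {
    it <- dataset[[i]]
    p <- mrdb_forward(array(it$image, c(1, 1, side, side)), model,
                      training = FALSE)[1, 1, , ]
    r <- metrics_report(p, it$mask > 0, threshold)
    rows[[i]] <- c(list(image_id = it$id), unclass(r))
    scores[[i]] <- p; gts[[i]] <- it$mask > 0
  }
  pr <- pr_curve(scores, gts)
  per_image <- do.call(rbind, lapply(rows, function(r)
    data.frame(image_id = r$image_id, dsc = r$dsc, jaccard = r$jaccard,
               sensitivity = r$sensitivity, hd95 = r$hd95, fnr = r$fnr)))
  summary <- list(dsc = mean(per_image$dsc), jaccard = mean(per_image$jaccard),
                  sensitivity = mean(per_image$sensitivity, na.rm = TRUE),
                  hd95 = mean(per_image$hd95, na.rm = TRUE),
                  fnr = mean(per_image$fnr, na.rm = TRUE),
                  pr_auc = pr$pr_auc)
  if (!is.null(out_csv)) write_metrics_csv(rows, out_csv)
  list(per_image = per_image, summary = summary)
}

#' Run the component ablation grid
#'
#' Instantiates the six cumulative configurations from
#' [ablation_configs()], trains each on the same dataset with the same
#' recipe, and reports first/final loss and final train-set Dice.
#'
#' @param dataset A `seg_dataset`.
#' @param cfg A [train_config()].
#' @param base_channels,state_dim Model width settings shared by all
#'   configurations.
#' @param verbose Print progress.
#' @return data.frame with one row per configuration.
#' @export
run_ablation <- function(dataset, cfg = train_config(), base_channels = 16L,
                         state_dim = 8L, verbose = FALSE) {
  cfgs <- ablation_configs(input_side = cfg$input_side,
                           base_channels = base_channels,
                           state_dim = state_dim)
  out <- NULL
  for (nm in names(cfgs)) {
    set.seed(cfg$seed)
    model <- mrdb_init(cfgs[[nm]])
    r <- train_mrdb(model, dataset, cfg, verbose = verbose)
    out <- rbind(out, data.frame(
      config = nm,
      first_loss = r$log$loss[1],
      final_loss = utils::tail(r$log$loss, 1),
      dsc = train_dsc(r$model, dataset, seq_along(dataset))))
    if (verbose) message(nm, ": loss ", round(out$final_loss[nrow(out)], 4))
  }
  out
}
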