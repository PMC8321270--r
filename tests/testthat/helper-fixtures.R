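# Shared fixtures: tiny phantom datasets and small network/training
# configurations, generated in code at test time.

tiny_phantom_config <- function(shape = c(48, 48, 48), seed = 11, ...) {
  phantom_config(shape = shape, lesion_count_mean = 2, lesion_count_min = 1,
                 lesion_count_max = 3, diameter_log_mean = log(8),
                 diameter_log_sd = 0.2, contrast_range = c(0.5, 0.7),
                 noise_sd = 0.05, seed = seed, ...)
}

tiny_net <- function(...) net_config(base_width = 4, ...)

tiny_train <- function(...) {
  train_config(epochs = 2, iters_per_epoch = 3, batch_size = 3,
               patch_size = c(32, 32, 32), lr_drop_epoch = 2, seed = 5, ...)
}

# small in-memory dataset (list of vol/mask arrays) without touching disk
make_cases <- function(n, config = tiny_phantom_config(), seed = 101) {
  lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    les <- sample_lesions(config)
    ph <- render_phantom(config, les)
    list(vol = ph$volume$data, mask = ph$mask$data, lesions = les,
         spacing = config$spacing)
  })
}

# one shared on-disk dataset + smoke-trained model per session, built
# lazily (used by training / inference / cli tests)
.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.fixture_env$manifest)) {
    dir <- file.path(tempdir(), "adaptseg-fixture-ds")
    manifest <- generate_dataset(tiny_phantom_config(), 4, dir)
    .fixture_env$manifest <- read_manifest(file.path(dir, "manifest.csv"))
    .fixture_env$dataset_dir <- dir
  }
  .fixture_env$manifest
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    man <- fixture_dataset()
    .fixture_env$ck1 <- train_stage1(man, tiny_net(), tiny_train(),
                                     verbose = FALSE)
    .fixture_env$ck2 <- train_stage2(man, .fixture_env$ck1, verbose = FALSE)
    .fixture_env$model <- structure(
      list(params = .fixture_env$ck2$params, net = .fixture_env$ck1$net,
           train = .fixture_env$ck1$train, seed = tiny_train()$seed,
           logs = list(stage1 = .fixture_env$ck1$log,
                       stage2 = .fixture_env$ck2$log)),
      class = "adaptseg_model")
  }
  .fixture_env$model
}

fixture_stage1_ckpt <- function() {
  fixture_model()
  .fixture_env$ck1
}

# independent R oracle: per-block maximum by explicit loops
oracle_block_max <- function(mask, k) {
  d <- dim(mask)
  od <- ceiling(d / k)
  out <- array(0, od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (l in seq_len(od[3])) {
    xs <- ((i - 1) * k + 1):min(i * k, d[1])
    ys <- ((j - 1) * k + 1):min(j * k, d[2])
    zs <- ((l - 1) * k + 1):min(l * k, d[3])
    out[i, j, l] <- max(mask[xs, ys, zs])
  }
  out
}

# independent R oracle: connected components by BFS queue
oracle_flood_fill <- function(bin, connectivity) {
  d <- dim(bin)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(bin)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        nb <- ci + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        w <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (bin[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# do two labelings induce the same partition of the foreground?
same_partition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0]; f2 <- lab2[lab2 > 0]
  if (length(f1) != length(f2)) return(FALSE)
  if (!identical(which(lab1 > 0), which(lab2 > 0))) return(FALSE)
  tab <- table(f1, f2)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
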