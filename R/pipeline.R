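# End-to-end pipeline: synthetic (or fixture) dyad sessions -> interbrain
# and envelope coupling maps (real + surrogate) -> bootstrap/FDR group
# statistics -> mediation regression -> exclusion mask.

#' Enumerate analysis cases
#'
#' Each dyad contributes two cases, one per role assignment (participant
#' A speaking and participant B speaking); 15 dyads give the 30-case
#' sample.
#'
#' @param n_dyads Number of dyads.
#' @return `data.frame(case, dyad, speaker)`.
#' @export
enumerate_cases <- function(n_dyads) {
  data.frame(case = seq_len(2L * n_dyads),
             dyad = rep(seq_len(n_dyads), each = 2L),
             speaker = rep(c("A", "B"), n_dyads))
}

#' Pipeline configuration
#'
#' @param synth A [synth_config()] describing the synthetic study, or
#'   `NULL` when `sessions` points at fixture directories.
#' @param sessions Character vector of session directories (see
#'   [read_session()]); ignored when `synth` is given.
#' @param bands Analysis bands; defaults to the synthesis bands or
#'   [canonical_bands()].
#' @param trim Edge samples removed before each PLV (default 1 s).
#' @param n_boot Bootstrap resamples for the group tests.
#' @param q FDR level for the synchronization maps.
#' @param mediation_alpha Uncorrected alpha for the mediation scan.
#' @param seed Master seed for the statistical resampling streams.
#' @param envelope Compute the envelope-entrainment branch (and with it
#'   the mediation scan and exclusion mask); `FALSE` runs the interbrain
#'   branch only.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param verbose Emit one progress line per stage.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(synth = NULL, sessions = NULL, bands = NULL,
                            trim = NULL, n_boot = 10000, q = 0.05,
                            mediation_alpha = 0.05, seed = 1, envelope = TRUE,
                            out_dir = NULL, verbose = FALSE) {
  if (is.null(synth) && is.null(sessions)) stop("either synth or sessions must be given")
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  if (is.null(bands)) bands <- if (!is.null(synth)) synth$bands else canonical_bands()
  bands <- as_band_list(bands)
  stopifnot(n_boot >= 1, q > 0, q < 1, mediation_alpha > 0, mediation_alpha < 1)
  structure(list(synth = synth, sessions = sessions, bands = bands,
                 trim = trim, n_boot = as.integer(n_boot), q = q,
                 mediation_alpha = mediation_alpha, seed = as.integer(seed),
                 envelope = isTRUE(envelope),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

# all coupling quantities for one case (one dyad, one role assignment)
case_compute <- function(session, speaker, bands, trim, envelope = TRUE) {
  listener <- if (speaker == "A") "B" else "A"
  liset <- session$epochs[[listener]]
  spset <- session$epochs[[speaker]]
  al <- align_trials(liset, spset)
  if (is.null(al$listener_rest) || is.null(al$speaker_rest)) {
    stop("both participants need a rest epoch")
  }
  topics <- al$topics
  n_topics <- length(topics)
  pairings <- enumerate_surrogate_pairings(n_topics)
  envs <- NULL
  if (envelope) {
    envs <- lapply(topics, function(tp) session$envelopes[[paste(tp, speaker, sep = ".")]]$values)
    if (any(vapply(envs, is.null, logical(1)))) stop("missing envelope for a speaking turn")
  }
  L <- length(liset$channels); S <- length(spset$channels)
  B <- length(bands)
  bb_real <- bb_surr <- array(NA_real_, dim = c(L, S, B),
                              dimnames = list(listener = liset$channels,
                                              speaker = spset$channels,
                                              band = names(bands)))
  env_mat <- function(chans) matrix(NA_real_, length(chans), B,
                                    dimnames = list(channel = chans, band = names(bands)))
  env_real_l <- env_surr_l <- env_mat(liset$channels)
  env_real_s <- env_surr_s <- env_mat(spset$channels)
  # stack each participant's epochs (topics 1..n, then rest) as rows so
  # one phasor pass yields the concatenated T x (n_topics*C + C) matrix
  li_stack <- do.call(rbind, c(lapply(al$listener, function(i) liset$epochs[[i]]$data),
                               list(al$listener_rest$data)))
  sp_stack <- do.call(rbind, c(lapply(al$speaker, function(i) spset$epochs[[i]]$data),
                               list(al$speaker_rest$data)))
  li_ph <- band_phasors(li_stack, bands, liset$rate, trim = trim)
  sp_ph <- band_phasors(sp_stack, bands, spset$rate, trim = trim)
  env_ph <- if (envelope) {
    env_stack <- do.call(rbind, lapply(envs, function(e) as.numeric(e) - mean(e)))
    band_phasors(env_stack, bands, liset$rate, trim = trim)
  } else NULL
  blk <- function(k, C) seq.int((k - 1L) * C + 1L, k * C)   # topic k's columns
  for (b in seq_len(B)) {
    li_all <- li_ph[[b]]
    sp_all <- sp_ph[[b]]
    G <- cpp_plv_cross(li_all, sp_all)
    rest_plv <- G[blk(n_topics + 1L, L), blk(n_topics + 1L, S), drop = FALSE]
    acc <- matrix(0, L, S)
    for (k in seq_len(n_topics)) acc <- acc + G[blk(k, L), blk(k, S), drop = FALSE]
    bb_real[, , b] <- acc / n_topics - rest_plv
    acc <- matrix(0, L, S)
    for (r in seq_len(nrow(pairings))) {
      acc <- acc + G[blk(pairings$listener_trial[r], L),
                     blk(pairings$speaker_trial[r], S), drop = FALSE]
    }
    bb_surr[, , b] <- acc / nrow(pairings) - rest_plv
    if (!envelope) next
    # envelope coupling, both roles, with intra-brain correction
    E <- env_ph[[b]]
    GL <- cpp_plv_cross(li_all, E)
    GS <- cpp_plv_cross(sp_all, E)
    li_intra <- cpp_intra_topic(li_all, L, n_topics)
    sp_intra <- cpp_intra_topic(sp_all, S, n_topics)
    ev_li <- vapply(seq_len(n_topics), function(k) GL[blk(k, L), k], numeric(L))
    ev_sp <- vapply(seq_len(n_topics), function(k) GS[blk(k, S), k], numeric(S))
    env_real_l[, b] <- rowMeans(ev_li) - mean(li_intra)
    env_real_s[, b] <- rowMeans(ev_sp) - mean(sp_intra)
    acc_l <- numeric(L); acc_s <- numeric(S)
    for (r in seq_len(nrow(pairings))) {
      i <- pairings$listener_trial[r]   # envelope topic
      j <- pairings$speaker_trial[r]    # EEG topic
      acc_l <- acc_l + GL[blk(j, L), i] - li_intra[j]
      acc_s <- acc_s + GS[blk(j, S), i] - sp_intra[j]
    }
    env_surr_l[, b] <- acc_l / nrow(pairings)
    env_surr_s[, b] <- acc_s / nrow(pairings)
  }
  list(bb_real = bb_real, bb_surr = bb_surr,
       env_real_l = env_real_l, env_surr_l = env_surr_l,
       env_real_s = env_real_s, env_surr_s = env_surr_s)
}

flatten_bb <- function(arr4) {
  d <- dim(arr4); dn <- dimnames(arr4)
  m <- matrix(arr4, nrow = d[1L])
  colnames(m) <- as.vector(outer(
    as.vector(outer(dn[[2L]], dn[[3L]], paste, sep = "|")), dn[[4L]], paste, sep = "|"))
  m
}

flatten_env <- function(arr_l, arr_s) {
  d <- dim(arr_l); dn <- dimnames(arr_l)
  ml <- matrix(arr_l, nrow = d[1L])
  ms <- matrix(arr_s, nrow = d[1L])
  nm <- as.vector(outer(dn[[2L]], dn[[3L]], paste, sep = "|"))
  colnames(ml) <- paste("listener", nm, sep = "|")
  colnames(ms) <- paste("speaker", nm, sep = "|")
  cbind(ml, ms)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) every dyad session, computes real and surrogate
#' interbrain and envelope coupling per case, runs the bootstrap/FDR
#' group statistics, the mediation regression scan and the final
#' exclusion mask, and optionally writes all tables.
#'
#' @param config A [pipeline_config()].
#' @return A `results_bundle` list; see the package vignette.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  bands <- cfg$bands
  say <- function(fmt, ...) if (cfg$verbose) message(sprintf(fmt, ...))
  sessions <- if (!is.null(cfg$synth)) seq_len(cfg$synth$n_dyads) else cfg$sessions
  n_dyads <- length(sessions)
  cases <- enumerate_cases(n_dyads)
  n_cases <- nrow(cases)
  bb_real <- bb_surr <- NULL
  env_real_l <- env_surr_l <- env_real_s <- env_surr_s <- NULL
  trim <- cfg$trim
  t0 <- proc.time()[["elapsed"]]
  for (d in seq_len(n_dyads)) {
    session <- if (!is.null(cfg$synth)) generate_dyad_session(cfg$synth, d)
               else read_session(sessions[[d]])
    if (is.null(trim)) trim <- round(session$rate)
    for (sp in c("A", "B")) {
      ci <- which(cases$dyad == d & cases$speaker == sp)
      res <- case_compute(session, sp, bands, trim, envelope = cfg$envelope)
      if (is.null(bb_real)) {
        dl <- dim(res$bb_real)
        mk4 <- function() array(NA_real_, c(n_cases, dl),
                                dimnames = c(list(case = NULL), dimnames(res$bb_real)))
        mk3 <- function(m) array(NA_real_, c(n_cases, dim(m)),
                                 dimnames = c(list(case = NULL), dimnames(m)))
        bb_real <- mk4(); bb_surr <- mk4()
        env_real_l <- mk3(res$env_real_l); env_surr_l <- mk3(res$env_real_l)
        env_real_s <- mk3(res$env_real_s); env_surr_s <- mk3(res$env_real_s)
      }
      bb_real[ci, , , ] <- res$bb_real; bb_surr[ci, , , ] <- res$bb_surr
      env_real_l[ci, , ] <- res$env_real_l; env_surr_l[ci, , ] <- res$env_surr_l
      env_real_s[ci, , ] <- res$env_real_s; env_surr_s[ci, , ] <- res$env_surr_s
    }
    say("dyad %d/%d: coupling maps done (%.1f s elapsed)", d, n_dyads,
        proc.time()[["elapsed"]] - t0)
  }
  set.seed(cfg$seed)
  seed_bb <- sample.int(.Machine$integer.max, 1L)
  seed_env <- sample.int(.Machine$integer.max, 1L)
  bb_real_m <- flatten_bb(bb_real); bb_surr_m <- flatten_bb(bb_surr)
  bb_stats <- group_test(bb_real_m, bb_surr_m, n_boot = cfg$n_boot, q = cfg$q, seed = seed_bb)
  bb_band <- factor(rep(names(bands), each = prod(dim(bb_real)[2:3])), levels = names(bands))
  bb_stats$band <- as.character(bb_band)
  say("interbrain stats: %d joint tests", nrow(bb_stats))
  bb_z <- zscore_map(bb_real_m, bb_surr_m, band = bb_band)
  enh <- bb_stats$significant & bb_stats$direction > 0
  bb_sig <- array(enh, dim = dim(bb_real)[2:4], dimnames = dimnames(bb_real)[2:4])
  env_res <- med <- excl <- NULL
  if (cfg$envelope) {
    env_real_m <- flatten_env(env_real_l, env_real_s)
    env_surr_m <- flatten_env(env_surr_l, env_surr_s)
    env_stats <- group_test(env_real_m, env_surr_m, n_boot = cfg$n_boot, q = cfg$q, seed = seed_env)
    nb_env <- dim(env_real_l)[3L]
    env_band <- factor(rep(rep(names(bands), each = dim(env_real_l)[2L]), 2L), levels = names(bands))
    env_role <- rep(c("listener", "speaker"), each = dim(env_real_l)[2L] * nb_env)
    env_stats$band <- as.character(env_band)
    env_stats$role <- env_role
    say("envelope stats: %d joint tests", nrow(env_stats))
    env_z <- zscore_map(env_real_m, env_surr_m, band = interaction(env_role, env_band))
    env_enh <- env_stats$significant & env_stats$direction > 0
    env_sig_l <- matrix(env_enh[env_role == "listener"], dim(env_real_l)[2L], nb_env,
                        dimnames = dimnames(env_real_l)[2:3])
    env_sig_s <- matrix(env_enh[env_role == "speaker"], dim(env_real_s)[2L], nb_env,
                        dimnames = dimnames(env_real_s)[2:3])
    env_res <- list(real_listener = env_real_l, real_speaker = env_real_s,
                    surrogate_listener = env_surr_l, surrogate_speaker = env_surr_s,
                    stats = env_stats, zmap = env_z,
                    significant_listener = env_sig_l, significant_speaker = env_sig_s)
    med <- mediation_scan(bb_real, env_real_l, env_real_s, alpha = cfg$mediation_alpha)
    say("mediation scan: %d fits", nrow(med))
    excl <- exclusion_mask(bb_sig, med, env_sig_l, env_sig_s)
    say("exclusion mask: %d surviving pairs", sum(excl$mask))
  }
  bundle <- structure(list(
    cases = cases,
    interbrain = list(real = bb_real, surrogate = bb_surr, stats = bb_stats,
                      zmap = bb_z, significant = bb_sig),
    envelope = env_res, mediation = med, exclusion = excl,
    provenance = pipeline_provenance(cfg, trim)
  ), class = "results_bundle")
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

pipeline_provenance <- function(cfg, trim) {
  synth <- cfg$synth
  list(
    package = "dyadsync",
    version = as.character(utils::packageVersion("dyadsync")),
    seed = cfg$seed, n_boot = cfg$n_boot, q = cfg$q,
    mediation_alpha = cfg$mediation_alpha, trim = trim,
    bands = data.frame(name = names(cfg$bands),
                       lo = vapply(cfg$bands, `[[`, numeric(1), "lo"),
                       hi = vapply(cfg$bands, `[[`, numeric(1), "hi")),
    synth = if (is.null(synth)) NULL else synth[setdiff(names(synth), "bands")]
  )
}

#' Write all result tables of a pipeline run
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, nm) write.table(x, file.path(dir, nm), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  tsv(bundle$interbrain$stats, "interbrain_stats.tsv")
  tsv(data.frame(feature = names(bundle$interbrain$zmap), z = bundle$interbrain$zmap),
      "interbrain_zmap.tsv")
  if (!is.null(bundle$envelope)) {
    tsv(bundle$envelope$stats, "envelope_stats.tsv")
    tsv(data.frame(feature = names(bundle$envelope$zmap), z = bundle$envelope$zmap),
        "envelope_zmap.tsv")
  }
  if (!is.null(bundle$mediation)) tsv(bundle$mediation, "mediation.tsv")
  if (!is.null(bundle$exclusion)) {
    tsv(bundle$exclusion$provenance, "exclusion_provenance.tsv")
    surv <- which(bundle$exclusion$mask, arr.ind = TRUE)
    dn <- dimnames(bundle$exclusion$mask)
    tsv(data.frame(listener = dn[[1L]][surv[, 1L]],
                   speaker = dn[[2L]][surv[, 2L]],
                   band = dn[[3L]][surv[, 3L]]),
        "exclusion_survivors.tsv")
  }
  prov <- bundle$provenance
  prov$bands <- NULL
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d cases; %d interbrain tests (%d significant)",
              nrow(x$cases), nrow(x$interbrain$stats),
              sum(x$interbrain$stats$significant)))
  if (!is.null(x$envelope)) {
    cat(sprintf("; %d envelope tests (%d significant); %d surviving pairs",
                nrow(x$envelope$stats), sum(x$envelope$stats$significant),
                sum(x$exclusion$mask)))
  }
  cat("\n")
  invisible(x)
}
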