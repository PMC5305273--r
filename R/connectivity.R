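# Network construction: random background wiring plus embedded assembly
# sequences.  A connectivity set stores one row per synapse; duplicate
# (pre, post) pairs arising from background + assembly wiring are merged by
# summing conductances, i.e. coincident connections double the weight.

SYN_CLASSES <- c("EE", "EI_onI", "IE_plastic", "II")

# Sample ordered pairs (pre in `pre_ids`) x (post in `post_ids`) each with
# independent probability p, excluding self-pairs.  Works in chunks over the
# linearised pair index so that a single Binomial draw + index sample gives
# the exact product-Bernoulli law at any size.
sample_pairs <- function(pre_ids, post_ids, p) {
  n_pre <- length(pre_ids)
  m <- length(post_ids)
  if (p <= 0 || n_pre == 0L || m == 0L) {
    return(list(pre = integer(0), post = integer(0)))
  }
  if (p > 1) stop("connection probability > 1")
  chunk <- max(1L, as.integer(2^30 %/% m))
  pre_out <- vector("list", ceiling(n_pre / chunk))
  post_out <- vector("list", ceiling(n_pre / chunk))
  ci <- 0L
  for (start in seq(1L, n_pre, by = chunk)) {
    ci <- ci + 1L
    ids <- pre_ids[start:min(n_pre, start + chunk - 1L)]
    npair <- length(ids) * m
    k <- rbinom(1L, npair, p)
    if (k == 0L) {
      pre_out[[ci]] <- integer(0)
      post_out[[ci]] <- integer(0)
      next
    }
    idx <- sample.int(npair, k)
    pre_out[[ci]] <- ids[(idx - 1L) %/% m + 1L]
    post_out[[ci]] <- post_ids[(idx - 1L) %% m + 1L]
  }
  pre <- unlist(pre_out, use.names = FALSE)
  post <- unlist(post_out, use.names = FALSE)
  keep <- pre != post
  list(pre = pre[keep], post = post[keep])
}

syn_class_of <- function(pre, post, N_E) {
  pe <- pre <= N_E
  po <- post <= N_E
  out <- character(length(pre))
  out[pe & po] <- "EE"
  out[pe & !po] <- "EI_onI"
  out[!pe & po] <- "IE_plastic"
  out[!pe & !po] <- "II"
  out
}

syn_table <- function(pre, post, g, delay) {
  data.frame(pre = as.integer(pre), post = as.integer(post),
             class = character(length(pre)), g_nS = rep_len(g, length(pre)),
             delay_ms = rep_len(delay, length(pre)), stringsAsFactors = FALSE)
}

new_connectivity <- function(synapses, spec, groups = list(), dummy = integer(0)) {
  structure(list(synapses = synapses, groups = groups, dummy = dummy,
                 spec = spec),
            class = "connectivity_set")
}

# Merge duplicate (pre, post) rows by summing conductances.  The synapse
# class is a function of the pre/post population identities, so duplicates
# always share it.
merge_synapses <- function(df, N_tot) {
  if (nrow(df) == 0L) return(df)
  key <- (as.numeric(df$pre) - 1) * N_tot + as.numeric(df$post)
  if (!anyDuplicated(key)) {
    return(df[order(key), , drop = FALSE])
  }
  g <- rowsum(df$g_nS, group = key, reorder = TRUE)
  ukey <- as.numeric(rownames(g))
  pre <- as.integer((ukey - 1) %/% N_tot + 1)
  post <- as.integer(ukey - (pre - 1) * N_tot)
  out <- data.frame(pre = pre, post = post,
                    class = character(length(pre)),
                    g_nS = as.numeric(g),
                    delay_ms = df$delay_ms[[1L]],
                    stringsAsFactors = FALSE)
  out
}

finalize_classes <- function(conn) {
  s <- conn$synapses
  if (nrow(s)) {
    s$class <- syn_class_of(s$pre, s$post, conn$spec$N_E)
    rownames(s) <- NULL
  }
  conn$synapses <- s
  conn
}

#' Build the random background network
#'
#' Connects every ordered pair of neurons (excluding self-connections)
#' independently with probability `p_rand`.  Excitatory-sourced synapses get
#' conductance `g_E`; inhibitory-to-excitatory synapses (the plastic class)
#' start at `g_EI_init`; inhibitory-to-inhibitory synapses get `g_I`.  All
#' delays equal `spec$delay`.  Neuron ids are `1..N_E` (excitatory) followed
#' by `N_E+1..N_E+N_I` (inhibitory).
#'
#' @param spec a [network_spec()].
#' @return A `connectivity_set`: a list with the synapse table
#'   (`pre`, `post`, `class`, `g_nS`, `delay_ms`), assembly membership
#'   (empty until a sequence is embedded), the dummy-group ids, and `spec`.
#' @export
#' @examples
#' conn <- build_background(network_spec(N_E = 200, N_I = 50, M = 20,
#'                                       n_groups = 2, p_rand = 0.05))
#' nrow(conn$synapses)
build_background <- function(spec) {
  validate_network_spec(spec)
  N <- spec$N_E + spec$N_I
  pr <- with_substream(spec$seed, "background",
                       sample_pairs(seq_len(N), seq_len(N), spec$p_rand))
  g <- ifelse(pr$pre <= spec$N_E, spec$g_E,
              ifelse(pr$post <= spec$N_E, spec$g_EI_init, spec$g_I))
  df <- syn_table(pr$pre, pr$post, g, spec$delay)
  conn <- new_connectivity(merge_synapses(df, N), spec)
  finalize_classes(conn)
}

# Sample disjoint assembly memberships and the dummy group.
sample_groups <- function(spec) {
  with_substream(spec$seed, "assemblies", {
    mE <- spec$M
    mI <- spec$M %/% 4L
    e_all <- sample.int(spec$N_E, spec$n_groups * mE)
    i_all <- if (spec$N_I > 0) sample.int(spec$N_I, spec$n_groups * mI) + spec$N_E
             else integer(0)
    groups <- lapply(seq_len(spec$n_groups), function(k) {
      list(E = sort(e_all[((k - 1) * mE + 1):(k * mE)]),
           I = if (length(i_all)) sort(i_all[((k - 1) * mI + 1):(k * mI)])
               else integer(0))
    })
    free <- setdiff(seq_len(spec$N_E), e_all)
    if (length(free) < mE) {
      stop("not enough background excitatory neurons left for the dummy group")
    }
    dummy <- sort(sample(free, mE))
    list(groups = groups, dummy = dummy)
  })
}

#' Embed a discrete assembly sequence
#'
#' Forms `n_groups` disjoint assemblies (each `M` excitatory plus `M/4`
#' inhibitory neurons sampled without replacement from the whole network),
#' wires every ordered pair within an assembly with probability `p_rc`, and
#' connects consecutive assemblies' excitatory populations in a feedforward
#' manner with probability `p_ff` and conductance `g_ff`.  In
#' `wiring_mode = "symmetric"`, backward projections (group *i* to *i-1*)
#' are added with the same probability, enabling reverse replay.  New
#' synapses are created in addition to the background ones: a pair connected
#' twice simply gets the summed (doubled) conductance.  A dummy group of `M`
#' background excitatory neurons is sampled once here and reused by the
#' replay scoring as a whole-network-activation detector.
#'
#' @param conn a `connectivity_set` from [build_background()].
#' @param spec optional spec override (defaults to `conn$spec`).
#' @return The augmented `connectivity_set` with `groups` and `dummy` filled.
#' @export
embed_sequence <- function(conn, spec = conn$spec) {
  stopifnot(inherits(conn, "connectivity_set"))
  validate_network_spec(spec)
  if (!spec$wiring_mode %in% c("feedforward", "symmetric")) {
    stop("embed_sequence: wiring_mode must be 'feedforward' or 'symmetric'")
  }
  mem <- sample_groups(spec)
  groups <- mem$groups
  N <- spec$N_E + spec$N_I

  add <- with_substream(spec$seed, "embedding", {
    pieces <- list()
    for (k in seq_along(groups)) {
      ids <- c(groups[[k]]$E, groups[[k]]$I)
      pr <- sample_pairs(ids, ids, spec$p_rc)
      if (length(pr$pre)) {
        g <- ifelse(pr$pre <= spec$N_E, spec$g_E,
                    ifelse(pr$post <= spec$N_E, spec$g_EI_init, spec$g_I))
        pieces[[length(pieces) + 1L]] <- syn_table(pr$pre, pr$post, g,
                                                   spec$delay)
      }
    }
    for (k in seq_len(length(groups) - 1L)) {
      pr <- sample_pairs(groups[[k]]$E, groups[[k + 1L]]$E, spec$p_ff)
      if (length(pr$pre)) {
        pieces[[length(pieces) + 1L]] <-
          syn_table(pr$pre, pr$post, spec$g_ff, spec$delay)
      }
      if (spec$wiring_mode == "symmetric") {
        pr <- sample_pairs(groups[[k + 1L]]$E, groups[[k]]$E, spec$p_ff)
        if (length(pr$pre)) {
          pieces[[length(pieces) + 1L]] <-
            syn_table(pr$pre, pr$post, spec$g_ff, spec$delay)
        }
      }
    }
    pieces
  })

  all_syn <- do.call(rbind, c(list(conn$synapses), add))
  out <- new_connectivity(merge_synapses(all_syn, N), spec,
                          groups = groups, dummy = mem$dummy)
  finalize_classes(out)
}

# window of up to M/2 positions on each side, truncated at the edges
cont_window <- function(i, half, n) {
  lo <- max(1L, i - half)
  hi <- min(n, i + half)
  setdiff(lo:hi, i)
}

#' Embed a continuous (assembly-free) sequence
#'
#' All excitatory neurons are arranged on a line in id order.  Each connects
#' with probability `p_rc` to the `M` nearest excitatory neighbours (`M/2`
#' preceding and `M/2` succeeding, truncated at the edges) and with
#' probability `p_ff` to the `M` cells in the forward window just beyond the
#' recurrent one (relative positions `(M/2, 3M/2]`).  Inhibitory neurons are
#' arranged on a parallel line at 1/4 density; their recurrent windows (size
#' `M/4`) and the cross-population windows are built analogously so that a
#' stretch of `M` excitatory cells and the matching `M/4` inhibitory cells
#' mirror one discrete assembly.
#'
#' @param conn a `connectivity_set` from [build_background()].
#' @param spec optional spec override with `wiring_mode = "continuous"`.
#' @return The augmented `connectivity_set`.  `groups` holds `n_groups`
#'   consecutive blocks of `M` excitatory ids (used by the replay metrics);
#'   the dummy group is drawn from the cells after the sequence if space
#'   permits, otherwise from the final block.
#' @export
embed_continuous_sequence <- function(conn, spec = conn$spec) {
  stopifnot(inherits(conn, "connectivity_set"))
  validate_network_spec(spec)
  if (spec$wiring_mode != "continuous") {
    stop("embed_continuous_sequence requires wiring_mode = 'continuous'")
  }
  M <- spec$M
  half <- M %/% 2L
  N_E <- spec$N_E
  N_I <- spec$N_I
  N <- N_E + N_I

  pieces <- with_substream(spec$seed, "embedding", {
    ps <- list()
    for (i in seq_len(N_E)) {
      rc <- cont_window(i, half, N_E)
      pr <- sample_pairs(i, rc, spec$p_rc)
      fwd_lo <- i + half + 1L
      fwd_hi <- min(N_E, i + half + M)
      fw <- if (fwd_lo <= fwd_hi) fwd_lo:fwd_hi else integer(0)
      pf <- sample_pairs(i, fw, spec$p_ff)
      pre <- c(pr$pre, pf$pre)
      post <- c(pr$post, pf$post)
      if (length(pre)) {
        g <- c(rep(spec$g_E, length(pr$pre)), rep(spec$g_ff, length(pf$pre)))
        ps[[length(ps) + 1L]] <- syn_table(pre, post, g, spec$delay)
      }
      # cross-population recurrence: E -> I within the matching window
      if (N_I > 0) {
        ci <- (i + 3L) %/% 4L
        iw <- cont_window(ci, M %/% 8L, N_I)
        iw <- c(iw, ci)
        pei <- sample_pairs(i, iw + N_E, spec$p_rc)
        if (length(pei$pre)) {
          ps[[length(ps) + 1L]] <- syn_table(pei$pre, pei$post, spec$g_E,
                                             spec$delay)
        }
      }
    }
    if (N_I > 0) {
      for (j in seq_len(N_I)) {
        # I -> I window on the inhibitory line
        iw <- cont_window(j, M %/% 8L, N_I)
        pii <- sample_pairs(j + N_E, iw + N_E, spec$p_rc)
        # I -> E window centred at the matching excitatory position
        ce <- 4L * j - 1L
        ew <- cont_window(ce, half, N_E)
        pie <- sample_pairs(j + N_E, ew, spec$p_rc)
        pre <- c(pii$pre, pie$pre)
        post <- c(pii$post, pie$post)
        if (length(pre)) {
          g <- c(rep(spec$g_I, length(pii$pre)),
                 rep(spec$g_EI_init, length(pie$pre)))
          ps[[length(ps) + 1L]] <- syn_table(pre, post, g, spec$delay)
        }
      }
    }
    ps
  })

  groups <- lapply(seq_len(spec$n_groups), function(k) {
    list(E = ((k - 1L) * M + 1L):(k * M),
         I = if (N_I > 0) (((k - 1L) * (M %/% 4L) + 1L):(k * (M %/% 4L))) + N_E
             else integer(0))
  })
  tail_start <- spec$n_groups * M + 1L
  dummy <- if (tail_start + M - 1L <= N_E) tail_start:(tail_start + M - 1L)
           else groups[[spec$n_groups]]$E

  all_syn <- do.call(rbind, c(list(conn$synapses), pieces))
  out <- new_connectivity(merge_synapses(all_syn, N), spec,
                          groups = groups, dummy = dummy)
  finalize_classes(out)
}

#' @export
print.connectivity_set <- function(x, ...) {
  cat("<connectivity_set>\n")
  cat(sprintf("  %d synapses over %d neurons (%d E + %d I)\n",
              nrow(x$synapses), x$spec$N_E + x$spec$N_I, x$spec$N_E,
              x$spec$N_I))
  if (nrow(x$synapses)) {
    print(table(x$synapses$class))
  }
  if (length(x$groups)) {
    cat(sprintf("  embedded sequence: %d groups (%s wiring), dummy group of %d\n",
                length(x$groups), x$spec$wiring_mode, length(x$dummy)))
  }
  invisible(x)
}
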