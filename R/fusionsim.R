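#' Simulate telomere fusion events with exact junction structure
#'
#' Draws `n` fusion events from the configured class mix (genomic,
#' intra-chromosomal sister chromatid, inter-chromosomal), with subtelomere
#' breakpoints placed by the deletion law (`deletion = telomere_boundary -
#' breakpoint`, uniform over `deletion_range`), microhomology lengths from a
#' geometric law of mean `mh_mean` truncated at `mh_max`, and insertions
#' (probability `ins_prob`, forcing MH to 0) that are either copied from a
#' flank within +/- `ins_window` bp of a breakpoint (templated) or random
#' (untemplated, verified absent from both flanks when length permits).
#'
#' Microhomology of length k is injected by overwriting the k junction-
#' proximal partner bases in the reference to match the subtelomere side,
#' and blocking the bases just beyond so the realised placement window is
#' exactly k wide. Because this patches the reference, the function returns
#' the patched reference together with the truth table; amplicon rendering
#' and downstream calling must use the returned `ref`. Patches never land on
#' bases another junction depends on (tracked via read/write masks), so
#' every junction's realised MH/INS equals its recorded truth, which is
#' re-verified against the final reference before returning.
#'
#' @param ref a `synthetic_reference` from [build_reference()].
#' @param cfg the [sim_config()] used to build it.
#' @param n number of fusions (>= 0).
#' @return a `fusion_sim` list: `truth` (data frame, one row per event:
#'   id, category, end_a, bp_a, chrom_b, strand_b, bp_b, len_b, mh_bp,
#'   ins_seq, ins_templated, del_a, del_b, delta_del) and `ref` (patched
#'   reference).
#' @export
simulate_fusions <- function(ref, cfg, n) {
  if (n < 0) stop("n must be >= 0")
  with_seed(derive_seed(cfg$seed, "fusions"), {
    sim_fusion_set(ref, cfg, n, simulant = FALSE)
  })
}

#' Generate simulant (null) fusions resolved by the identical methodology
#'
#' Simulants form the null distribution for enrichment statistics: their
#' subtelomere breakpoints are uniform between primer and telomere boundary,
#' partner coordinates uniform over the genome, junctions carry no
#' microhomology and no insertion (enforced by rejection, never by editing
#' the reference), and their amplicons/reads are produced by the identical
#' rendering and read-generation path as biological fusions.
#'
#' @param ref a `synthetic_reference`.
#' @param n number of simulants (>= 1).
#' @param cfg a [sim_config()].
#' @param with_reads also render amplicons and generate reads (default TRUE).
#' @return a `fusion_sim` list (`truth`, `ref` (unmodified), and when
#'   `with_reads` also `amplicons` and `reads`).
#' @export
generate_simulants <- function(ref, n, cfg, with_reads = TRUE) {
  if (n < 1) stop("n must be >= 1")
  sim <- with_seed(derive_seed(cfg$seed, "simulants"), {
    sim_fusion_set(ref, cfg, n, simulant = TRUE)
  })
  if (with_reads) {
    sim$amplicons <- render_amplicons(sim$truth, sim$ref)
    sim$reads <- with_seed(derive_seed(cfg$seed, "simulant_reads"),
                           generate_reads(sim$amplicons, cfg))
  }
  sim
}

# shared machinery for biological fusions (patching) and simulants (rejection)
sim_fusion_set <- function(ref, cfg, n, simulant = FALSE) {
  subtels <- ref$subtelomeres
  targets <- targeted_ends(ref)
  chroms <- names(ref$minigenome)
  clens <- chrom_sizes(ref)
  primer <- cfg$primer_offset
  boundary <- cfg$telomere_boundary
  min_apart <- 50L # keep the A segment anchorable by seeds

  env <- new.env(parent = emptyenv())
  env$seqs <- c(as.list(ref$subtel_seqs), as.list(ref$minigenome))
  env$readm <- lapply(env$seqs, function(s) logical(nchar(s)))
  env$writem <- lapply(env$seqs, function(s) logical(nchar(s)))

  base_at <- function(nm, pos0) substr(env$seqs[[nm]], pos0 + 1L, pos0 + 1L)
  mark <- function(mask, nm, lo0, hi0) {
    v <- env[[mask]][[nm]]
    v[(lo0 + 1L):(hi0 + 1L)] <- TRUE
    env[[mask]][[nm]] <- v
  }
  is_free_for_write <- function(nm, lo0, hi0) {
    idx <- (lo0 + 1L):(hi0 + 1L)
    !any(env$readm[[nm]][idx]) && !any(env$writem[[nm]][idx])
  }
  is_free_for_read <- function(nm, lo0, hi0) {
    !any(env$writem[[nm]][(lo0 + 1L):(hi0 + 1L)])
  }
  poke <- function(nm, pos0, chars) {
    s <- env$seqs[[nm]]
    substr(s, pos0 + 1L, pos0 + length_chars(chars)) <- collapse_chars(chars)
    env$seqs[[nm]] <- s
  }

  ltr_of <- function(end_id) {
    s <- subtels[subtels$end_id == end_id, ]
    c(s$ltr_start, s$ltr_end)
  }

  draw_bp_a <- function(end_id) {
    repeat {
      if (simulant) {
        bp <- primer + sample.int(boundary - primer, 1L)
      } else {
        del <- cfg$deletion_range[1] +
          sample.int(cfg$deletion_range[2] - cfg$deletion_range[1] + 1L,
                     1L) - 1L
        bp <- boundary - del
      }
      if (bp - primer < min_apart && !simulant) next
      if (bp <= primer || bp > boundary) next
      if (!simulant && cfg$ltr_avoid > 0) {
        ltr <- ltr_of(end_id)
        if (bp > ltr[1] && bp <= ltr[2] && stats::runif(1) < cfg$ltr_avoid)
          next
      }
      return(bp)
    }
  }

  cats <- c("genomic", "intra", "inter")
  out <- vector("list", n)
  if (n == 0L) {
    return(empty_fusion_sim(ref))
  }
  for (i in seq_len(n)) {
    # the event's class and junction structure are drawn once; conflicts
    # during placement only redraw coordinates, so the class mix and the
    # MH/INS laws are not biased by placement rejection
    category <- sample(cats, 1L, prob = cfg$class_mix)
    if (simulant) {
      k <- 0L; ins <- ""; ins_tmpl <- NA
    } else if (stats::runif(1) < cfg$ins_prob) {
      k <- 0L
      ins_len <- cfg$ins_len_range[1] +
        sample.int(diff(cfg$ins_len_range) + 1L, 1L) - 1L
      ins_tmpl <- stats::runif(1) < cfg$ins_templated_prob
      ins <- NULL # drawn after the partner is known
    } else {
      k <- min(stats::rgeom(1L, 1 / (1 + cfg$mh_mean)), cfg$mh_max)
      ins <- ""; ins_tmpl <- NA
    }
    has_ins <- isTRUE(ins_tmpl) || isFALSE(ins_tmpl)
    committed <- FALSE
    tries <- 0L
    while (!committed) {
      tries <- tries + 1L
      if (tries > 5000L) stop("could not place fusion ", i,
                              " without conflicting junction constraints")
      # under heavy junction-window congestion, degrade the requested MH
      # (or templated flag) rather than fail; the truth records what was
      # actually placed
      if (tries %% 150L == 0L) {
        if (!has_ins && k > 0L) k <- k - 1L
        if (has_ins && isTRUE(ins_tmpl) && tries >= 600L) ins_tmpl <- FALSE
      }
      end_a <- targets[sample.int(length(targets), 1L)]
      bp_a <- draw_bp_a(end_a)

      # partner draw
      if (category == "genomic") {
        ci <- sample.int(length(chroms), 1L, prob = clens / sum(clens))
        nm_b <- chroms[ci]
        strand_b <- sample(c("+", "-"), 1L)
        len_b <- cfg$partner_len_range[1] +
          sample.int(diff(cfg$partner_len_range) + 1L, 1L) - 1L
        L <- clens[ci]
        if (strand_b == "+") {
          lo <- cfg$mh_max + 2L
          hi <- L - len_b
        } else {
          lo <- len_b
          hi <- L - cfg$mh_max - 2L
        }
        if (hi <= lo) next
        pb <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        primer_b <- NA_integer_
      } else {
        nm_b <- if (category == "intra") end_a else {
          others <- setdiff(targets, end_a)
          others[sample.int(length(others), 1L)]
        }
        strand_b <- "-"
        pb <- if (simulant) {
          primer + sample.int(boundary - primer, 1L)
        } else {
          del_b <- cfg$deletion_range[1] +
            sample.int(cfg$deletion_range[2] - cfg$deletion_range[1] + 1L,
                       1L) - 1L
          boundary - del_b
        }
        if (!simulant && pb - primer < min_apart) next
        if (pb <= primer || pb > boundary) next
        len_b <- pb - primer
        primer_b <- primer
      }

      if (has_ins) {
        res <- draw_insertion(env, cfg, end_a, bp_a, nm_b, strand_b, pb,
                              ins_len, ins_tmpl, base_at)
        if (is.null(res)) next
        ins <- res$ins
        read_windows <- res$read_windows
        write_plan <- NULL
        # edge-blocking read windows at both junction flanks
        read_windows <- c(read_windows, list(
          list(nm = end_a, lo = bp_a - 1L, hi = bp_a),
          partner_block_window(nm_b, strand_b, pb, 0L)))
        ok_edges <- ins_edges_ok(env, ins, end_a, bp_a, nm_b, strand_b, pb,
                                 base_at)
        if (!ok_edges) next
      } else if (k == 0L) {
        # rejection: block extension on both sides without editing
        cont_b <- partner_first_base(env, nm_b, strand_b, pb, base_at)
        lead_b <- partner_lead_base(env, nm_b, strand_b, pb, base_at)
        if (identical(cont_b, base_at(end_a, bp_a))) next
        if (identical(lead_b, base_at(end_a, bp_a - 1L))) next
        read_windows <- list(
          list(nm = end_a, lo = bp_a - 1L, hi = bp_a),
          partner_block_window(nm_b, strand_b, pb, 0L))
        write_plan <- NULL
      } else {
        # write plan: overwrite k junction-proximal partner bases to match
        # the subtelomere side, and block one base beyond on each side
        tmpl <- substr(env$seqs[[end_a]], bp_a + 1L, bp_a + k)
        wk <- partner_block_window(nm_b, strand_b, pb, k)
        read_windows <- list(list(nm = end_a, lo = bp_a - 1L, hi = bp_a + k))
        write_plan <- list(nm = nm_b, strand = strand_b, pb = pb, k = k,
                           tmpl = tmpl,
                           block_cont = base_at(end_a, bp_a + k),
                           block_lead = base_at(end_a, bp_a - 1L),
                           lo = wk$lo, hi = wk$hi)
      }

      # a near-palindromic placement can put the MH patch on top of this
      # event's own template window; redraw coordinates in that case
      if (!is.null(write_plan)) {
        self_hit <- any(vapply(read_windows, function(w) {
          w$nm == write_plan$nm && w$lo <= write_plan$hi &&
            write_plan$lo <= w$hi
        }, logical(1)))
        if (self_hit) next
      }

      # conflict checks against prior junctions
      ok <- TRUE
      for (w in read_windows) {
        lo <- max(0L, w$lo); hi <- w$hi
        if (hi < lo) next
        if (!is_free_for_read(w$nm, lo, hi)) { ok <- FALSE; break }
      }
      if (ok && !is.null(write_plan)) {
        if (!is_free_for_write(write_plan$nm, write_plan$lo, write_plan$hi))
          ok <- FALSE
      }
      if (!ok) next

      # commit
      if (!is.null(write_plan)) {
        apply_mh_patch(env, write_plan, poke)
        mark("writem", write_plan$nm, write_plan$lo, write_plan$hi)
      }
      for (w in read_windows) {
        lo <- max(0L, w$lo); hi <- w$hi
        if (hi >= lo) mark("readm", w$nm, lo, hi)
      }
      del_a <- boundary - bp_a
      del_b <- if (category == "genomic") NA_integer_ else boundary - pb
      out[[i]] <- data.frame(
        id = sprintf("F%05d", i), category = category, end_a = end_a,
        bp_a = bp_a, chrom_b = nm_b, strand_b = strand_b, bp_b = pb,
        len_b = len_b, mh_bp = as.integer(k), ins_seq = ins,
        ins_templated = if (nchar(ins) > 0) ins_tmpl else NA,
        del_a = as.integer(del_a), del_b = del_b,
        delta_del = if (category == "intra") abs(del_a - del_b) else
          NA_integer_,
        stringsAsFactors = FALSE)
      committed <- TRUE
    }
  }
  truth <- do.call(rbind, out)

  ref2 <- ref
  ref2$subtel_seqs <- unlist(env$seqs[names(ref$subtel_seqs)])
  ref2$minigenome <- unlist(env$seqs[names(ref$minigenome)])

  # verify every junction's realised structure against the final reference
  if (!simulant && nrow(truth) > 0) {
    chk <- resolve_truth_junctions(truth, ref2)
    bad <- which(chk$mh_bp != truth$mh_bp | chk$ins_seq != truth$ins_seq)
    if (length(bad) > 0)
      stop("internal error: ", length(bad),
           " junction(s) failed truth verification")
    # realised templating status against the final patched reference
    has <- nchar(truth$ins_seq) > 0
    if (any(has)) {
      truth$ins_templated[has] <- vapply(which(has), function(i) {
        identical(classify_insertion(
          truth$ins_seq[i], ref_sequence(ref2, truth$end_a[i]),
          ref_sequence(ref2, truth$chrom_b[i]),
          truth$bp_a[i], truth$bp_b[i], window = cfg$ins_window),
          "templated")
      }, logical(1))
    }
  }

  structure(list(truth = truth, ref = ref2), class = "fusion_sim")
}

empty_fusion_sim <- function(ref) {
  truth <- data.frame(id = character(), category = character(),
                      end_a = character(), bp_a = integer(),
                      chrom_b = character(), strand_b = character(),
                      bp_b = integer(), len_b = integer(), mh_bp = integer(),
                      ins_seq = character(), ins_templated = logical(),
                      del_a = integer(), del_b = integer(),
                      delta_del = integer(), stringsAsFactors = FALSE)
  structure(list(truth = truth, ref = ref), class = "fusion_sim")
}

# ---- partner-side geometry helpers (0-based junction coordinate pb) -------

# first partner base entering the amplicon after the junction
partner_first_base <- function(env, nm, strand, pb, base_at) {
  if (strand == "+") base_at(nm, pb) else comp_base(base_at(nm, pb - 1L))
}

# reference base just before the junction on the partner side (lead-in)
partner_lead_base <- function(env, nm, strand, pb, base_at) {
  if (strand == "+") base_at(nm, pb - 1L) else comp_base(base_at(nm, pb))
}

# window of partner bases that an MH-k patch occupies (plus blocking bases)
partner_block_window <- function(nm, strand, pb, k) {
  if (strand == "+") list(nm = nm, lo = pb - 1L, hi = pb + k) else
    list(nm = nm, lo = pb - k - 1L, hi = pb)
}

apply_mh_patch <- function(env, wp, poke) {
  k <- wp$k
  tmpl_chars <- strsplit(wp$tmpl, "", fixed = TRUE)[[1]]
  if (wp$strand == "+") {
    poke(wp$nm, wp$pb, tmpl_chars)
    poke(wp$nm, wp$pb + k, other_base(wp$block_cont))
    poke(wp$nm, wp$pb - 1L, other_base(wp$block_lead))
  } else {
    poke(wp$nm, wp$pb - k, rev(vapply(tmpl_chars, comp_base, character(1),
                                      USE.NAMES = FALSE)))
    poke(wp$nm, wp$pb - k - 1L, other_base(comp_base(wp$block_cont)))
    poke(wp$nm, wp$pb, other_base(comp_base(wp$block_lead)))
  }
}

length_chars <- function(x) length(x)
collapse_chars <- function(x) paste(x, collapse = "")

# draw an insertion consistent with its truth flag; NULL to force a redraw
draw_insertion <- function(env, cfg, end_a, bp_a, nm_b, strand_b, pb,
                           ins_len, templated, base_at) {
  w <- cfg$ins_window
  seq_a <- env$seqs[[end_a]]
  seq_b <- env$seqs[[nm_b]]
  if (templated) {
    for (try in 1:60) {
      side <- sample(c("A", "B"), 1L)
      rc <- sample(c(TRUE, FALSE), 1L)
      ref <- if (side == "A") seq_a else seq_b
      bp <- if (side == "A") bp_a else pb
      lo <- max(1L, bp - w + 1L)
      hi <- min(nchar(ref), bp + w) - ins_len + 1L
      if (hi < lo) next
      st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      ins <- substr(ref, st, st + ins_len - 1L)
      if (rc) ins <- revcomp(ins)
      if (ins_edges_ok(env, ins, end_a, bp_a, nm_b, strand_b, pb, base_at))
        return(list(ins = ins,
                    read_windows = list(list(
                      nm = if (side == "A") end_a else nm_b,
                      lo = st - 1L, hi = st + ins_len - 2L))))
    }
    return(NULL)
  }
  # untemplated: random, and for longer insertions verified absent from
  # both +/- window flanks (both strands) so the classifier's answer is
  # unambiguous
  flank <- function(ref, bp) {
    substr(ref, max(1L, bp - w + 1L), min(nchar(ref), bp + w))
  }
  fl <- c(flank(seq_a, bp_a), flank(seq_b, pb))
  for (try in 1:60) {
    ins <- random_dna(ins_len)
    if (!ins_edges_ok(env, ins, end_a, bp_a, nm_b, strand_b, pb, base_at))
      next
    if (ins_len >= 4L) {
      pats <- c(ins, revcomp(ins))
      if (any(vapply(pats, function(p) any(grepl(p, fl, fixed = TRUE)),
                     logical(1)))) next
    }
    return(list(ins = ins, read_windows = list()))
  }
  NULL
}

# the insertion must not extend either flank (keeps truth MH = 0 and the
# realised insertion exactly the recorded one)
ins_edges_ok <- function(env, ins, end_a, bp_a, nm_b, strand_b, pb, base_at) {
  first <- substr(ins, 1L, 1L)
  last <- substr(ins, nchar(ins), nchar(ins))
  if (identical(first, base_at(end_a, bp_a))) return(FALSE)
  lead <- partner_lead_base(env, nm_b, strand_b, pb, base_at)
  !identical(last, lead)
}
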