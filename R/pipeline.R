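#' Default pipeline configuration
#'
#' Flat list of every tunable threshold in the stage sequence, with the
#' package defaults: `iou_min` 0.7 and `min_len` 25 (consensus),
#' `score_min` 0.5 (label assignment), `dist_max` 8, `min_pairs` 3 and
#' `pae_max` 10 (interaction filters), `k` 5 and `glob_max` 1.5
#' (novelty triage), `z_min` 9 (symmetry gate), `min_shift` 8 and
#' `dist_cutoff` 4 (symmetry scan), and `seed`.
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(iou_min = 0.7, min_len = 25, score_min = 0.5,
                 dist_max = 8, min_pairs = 3, pae_max = 10,
                 k = 5, z_min = 9, glob_max = 1.5,
                 min_shift = 8, dist_cutoff = 4, seed = 1),
            class = "run_config")
}

#' Read / write a pipeline configuration file
#'
#' Flat `key = value` text format; unknown keys are rejected, missing
#' keys take their defaults. Round-trips through [write_run_config()].
#'
#' @param path config file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- as.numeric(trimws(kv[2]))
  }
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(sprintf("%s = %.10g", names(cfg), unlist(cfg)), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$iou_min >= 0, cfg$iou_min <= 1, cfg$min_len >= 1,
            cfg$score_min >= 0, cfg$score_min <= 1,
            cfg$dist_max > 0, cfg$min_pairs >= 1, cfg$pae_max > 0,
            cfg$k >= 1, cfg$glob_max > 0, cfg$min_shift >= 1,
            cfg$dist_cutoff > 0)
  invisible(cfg)
}

#' Generate a self-contained pipeline input directory
#'
#' Writes the full input dialect consumed by [run_pipeline()]: one PDB
#' and one PAE JSON per chain, a long-form `choppings.tsv` with three
#' methods per chain (the ground truth jittered independently per
#' method), `hits.tsv` with structure-search and nearest-neighbour hits
#' for a labelled majority of domains, and `embeddings.tsv` /
#' `refs.tsv` for novelty scoring of the unlabelled remainder. Ground
#' truth (per-chain layouts and planted label status) is returned for
#' self-grading tests.
#'
#' @param dir output directory (created if needed).
#' @param n_chains number of chains (default 20).
#' @param seed RNG seed.
#' @return invisibly, a list with `layouts` and the planted `label_kind`
#'   per domain ("H", "T" or "none").
#' @export
make_pipeline_fixture <- function(dir, n_chains = 20, seed = 1) {
  dir.create(file.path(dir, "chains"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pae"), recursive = TRUE, showWarnings = FALSE)
  codes <- c("3.40.50.300", "2.60.40.10", "1.10.510.10", "3.30.200.20",
             "2.40.30.200", "3.40.50.720")
  with_seed(seed, {
    chop_rows <- list(); hit_rows <- list(); emb_rows <- list()
    layouts <- list(); label_kind <- character(0)
    for (c_i in seq_len(n_chains)) {
      chain_id <- sprintf("CH%03d", c_i)
      n_dom <- sample(1:3, 1)
      layout <- sample(seq(40, 90, by = 5), n_dom, replace = TRUE)
      layouts[[chain_id]] <- layout
      fx <- make_chain(layout, seed = sample.int(1e6, 1), chain_id = chain_id)
      write_structure(fx$chain, file.path(dir, "chains", paste0(chain_id, ".pdb")))
      seg_layout <- diff(c(0, cumsum(c(rbind(layout, 5))[-2 * length(layout)])))
      pae <- make_pae(seg_layout, intra_level = 3, inter_level = 6,
                      noise_sigma = 0.3, seed = sample.int(1e6, 1))
      write_pae(pae, file.path(dir, "pae", paste0(chain_id, ".json")))
      truth <- chopping_residues(fx$chopping)
      for (method in c("merizo", "chainsaw", "unidoc")) {
        # boundary jitter capped at +/-2 so jittered domains stay disjoint
        # across the 5-residue linkers
        jit <- lapply(truth, function(res) {
          a <- min(res) + sample(-2:2, 1); b <- max(res) + sample(-2:2, 1)
          seq.int(max(1L, a), min(length(fx$chain), b))
        })
        chop_rows[[length(chop_rows) + 1L]] <- data.frame(
          chain_id = chain_id, method = method,
          chopping = format_chopping(
            chopping(lapply(jit, segments_from_residues), source = method)),
          stringsAsFactors = FALSE)
      }
      for (d in seq_along(layout)) {
        dom_id <- sprintf("%s_D%02d", chain_id, d)
        kind <- sample(c("H", "T", "none"), 1, prob = c(0.7, 0.15, 0.15))
        label_kind <- c(label_kind, setNames(kind, dom_id))
        if (kind == "H") {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            query = dom_id, target_code = sample(codes, 1),
            score = round(runif(1, 0.75, 0.99), 4),
            kind = "structure_search", stringsAsFactors = FALSE)
        } else if (kind == "T") {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            query = dom_id, target_code = sample(codes, 1),
            score = round(runif(1, 0.3, 0.9), 4),
            kind = "nearest_neighbour", stringsAsFactors = FALSE)
        }
        emb_rows[[length(emb_rows) + 1L]] <- data.frame(
          domain_id = dom_id,
          t(round(rnorm(16) + if (kind == "none") 4 else 0, 6)),
          stringsAsFactors = FALSE)
      }
    }
    write_tsv(do.call(rbind, chop_rows), file.path(dir, "choppings.tsv"))
    write_tsv(do.call(rbind, hit_rows), file.path(dir, "hits.tsv"))
    emb <- do.call(rbind, emb_rows)
    names(emb) <- c("domain_id", paste0("e", 1:16))
    write_tsv(emb, file.path(dir, "embeddings.tsv"))
    refs <- make_embeddings(60, dim = 16, seed = sample.int(1e6, 1))
    write_tsv(data.frame(domain_id = rownames(refs), round(refs, 6),
                         stringsAsFactors = FALSE,
                         row.names = NULL) |>
                setNames(c("domain_id", paste0("e", 1:16))),
              file.path(dir, "refs.tsv"))
    invisible(list(layouts = layouts, label_kind = label_kind))
  })
}

#' Run the full desk-scale pipeline over an input directory
#'
#' Executes the stage sequence consensus -> classification -> routing ->
#' interactions (labelled domains) / novelty triage (unlabelled), and
#' writes per-stage TSVs plus a run summary to `out_dir`. All stages are
#' pure functions of (inputs, config), so reruns with the same inputs
#' and config are byte-identical.
#'
#' Expected input layout under `in_dir`: `chains/<id>.pdb`,
#' `pae/<id>.json`, `choppings.tsv` (chain_id, method, chopping),
#' `hits.tsv` (query, target_code, score, kind), `embeddings.tsv` and
#' `refs.tsv` (domain_id plus embedding columns).
#'
#' Outputs: `consensus.tsv`, `labels.tsv`, `isps.tsv`,
#' `graph_edges.tsv`, `graph_nodes.tsv`, `novelty.tsv`, `summary.tsv`
#' and `config.txt`. On any stage error the partial outputs are removed
#' before the error propagates.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created).
#' @param config a `run_config` list or path to a config file.
#' @return invisibly, the run summary as a data.frame.
#' @export
run_pipeline <- function(in_dir, out_dir, config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  chop_path <- file.path(in_dir, "choppings.tsv")
  if (!file.exists(chop_path))
    stop("consensus stage: missing input ", chop_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    written <<- c(written, p)
    p
  }
  on.exit(unlink(written))  # cancelled on success

  chops <- read_tsv(chop_path)
  chain_ids <- sort(unique(chops$chain_id))
  chains <- list(); consensus <- list(); cons_rows <- list()
  for (cid in chain_ids) {
    pdb <- file.path(in_dir, "chains", paste0(cid, ".pdb"))
    if (!file.exists(pdb)) stop("consensus stage: missing structure ", pdb)
    chain <- read_structure(pdb)
    chain$chain_id <- cid
    sub <- chops[chops$chain_id == cid, , drop = FALSE]
    if (nrow(sub) != 3L)
      stop("consensus stage: chain ", cid, " needs exactly 3 choppings, got ",
           nrow(sub))
    sub <- sub[order(sub$method), , drop = FALSE]
    parsed <- lapply(seq_len(3), function(i)
      parse_chopping(sub$chopping[i], source = sub$method[i]))
    res <- consensus_assign(parsed[[1]], parsed[[2]], parsed[[3]],
                            iou_min = config$iou_min,
                            min_len = config$min_len, chain = chain)
    chains[[cid]] <- chain; consensus[[cid]] <- res
    ndr_frac <- length(res$ndr_residues) / length(chain)
    for (d in seq_along(res$domains)) {
      dom <- res$domains[[d]]
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        chain_id = cid, domain_idx = d,
        domain_id = sprintf("%s_D%02d", cid, d),
        chopping = format_chopping(chopping(list(dom$segments))),
        confidence = dom$confidence,
        n_methods = length(dom$supporting_methods),
        avg_plddt = round(dom$avg_plddt, 2),
        plddt_bin = plddt_bin(dom$avg_plddt),
        ndr_fraction = round(ndr_frac, 4), stringsAsFactors = FALSE)
    }
  }
  cons_df <- if (length(cons_rows)) do.call(rbind, cons_rows) else
    data.frame(chain_id = character(0), domain_idx = integer(0),
               domain_id = character(0), chopping = character(0),
               confidence = character(0), n_methods = integer(0),
               avg_plddt = numeric(0), plddt_bin = character(0),
               ndr_fraction = numeric(0))
  emit(cons_df, "consensus.tsv")

  hits_path <- file.path(in_dir, "hits.tsv")
  if (!file.exists(hits_path)) stop("classification stage: missing ", hits_path)
  hits <- read_tsv(hits_path)
  lab_rows <- lapply(cons_df$domain_id, function(did) {
    lab <- assign_label(hits[hits$query == did, , drop = FALSE],
                        score_min = config$score_min)
    data.frame(domain_id = did, level = lab$level,
               code = if (lab$level == "none") NA_character_ else format(lab$code),
               source = lab$source, stringsAsFactors = FALSE)
  })
  lab_df <- if (length(lab_rows)) do.call(rbind, lab_rows) else
    data.frame(domain_id = character(0), level = character(0),
               code = character(0), source = character(0))
  emit(lab_df, "labels.tsv")

  # interactions over H-labelled domains
  h_labels <- lab_df[lab_df$level == "H", c("domain_id", "code")]
  chain_recs <- lapply(chain_ids, function(cid) {
    pae_path <- file.path(in_dir, "pae", paste0(cid, ".json"))
    if (!file.exists(pae_path))
      stop("interactions stage: missing PAE ", pae_path)
    list(chain = chains[[cid]], consensus = consensus[[cid]],
         labels = h_labels, pae = read_pae(pae_path))
  })
  isps <- extract_isps(chain_recs, dist_max = config$dist_max,
                       min_pairs = config$min_pairs, pae_max = config$pae_max)
  num <- vapply(isps, is.numeric, logical(1))
  isps[num] <- lapply(isps[num], round, 4)
  emit(isps, "isps.tsv")
  isp_sum <- summarize_isps(isps)
  graph <- export_interaction_graph(isp_sum)
  emit(graph$edges, "graph_edges.tsv")
  emit(graph$nodes, "graph_nodes.tsv")

  # novelty triage over unlabelled domains
  emb_path <- file.path(in_dir, "embeddings.tsv")
  refs_path <- file.path(in_dir, "refs.tsv")
  if (!file.exists(emb_path) || !file.exists(refs_path))
    stop("novelty stage: missing embeddings or refs table")
  emb <- read_tsv(emb_path)
  refs_df <- read_tsv(refs_path)
  refs <- as.matrix(refs_df[, -1]); rownames(refs) <- refs_df[[1]]
  unlab <- cons_df$domain_id[cons_df$domain_id %in%
                               lab_df$domain_id[lab_df$level == "none"]]
  reps <- lapply(unlab, function(did) {
    cid <- cons_df$chain_id[cons_df$domain_id == did]
    idx <- cons_df$domain_idx[cons_df$domain_id == did]
    res <- consensus[[cid]]$domains[[idx]]$residues
    chain <- chains[[cid]]
    coords <- chain_coords(chain, res)
    z <- if (nrow(coords) >= 2 * config$min_shift)
      symmetry_scan(coords, min_shift = config$min_shift,
                    dist_cutoff = config$dist_cutoff)$zscore else NA_real_
    erow <- emb[emb$domain_id == did, -1, drop = FALSE]
    if (nrow(erow) != 1L) stop("novelty stage: no embedding for ", did)
    list(domain_id = did, zscore = z, globularity = globularity(coords),
         embedding = as.numeric(erow[1, ]))
  })
  nov <- if (length(reps) > 0L)
    triage_unlabelled(reps, refs, k = config$k, z_min = config$z_min,
                      glob_max = config$glob_max)
  else data.frame(domain_id = character(0), route = character(0),
                  globularity = numeric(0), zscore = numeric(0),
                  novelty_score = numeric(0), knn_dist = numeric(0))
  num <- vapply(nov, is.numeric, logical(1))
  nov[num] <- lapply(nov[num], round, 4)
  emit(nov, "novelty.tsv")

  summary_df <- data.frame(
    metric = c("n_chains", "n_consensus_domains", "n_high", "n_medium",
               "n_labelled_H", "n_labelled_T", "n_unlabelled",
               "n_isp_instances", "n_isps", "n_novel_candidates",
               "n_repeat_category", "n_discarded_poor_quality"),
    value = c(length(chain_ids), nrow(cons_df),
              sum(cons_df$confidence == "high"),
              sum(cons_df$confidence == "medium"),
              sum(lab_df$level == "H"), sum(lab_df$level == "T"),
              sum(lab_df$level == "none"),
              nrow(isps), nrow(isp_sum),
              sum(nov$route == "novel_candidate"),
              sum(nov$route == "repeat_category"),
              sum(nov$route == "discarded_poor_quality")))
  emit(summary_df, "summary.tsv")
  write_run_config(config, file.path(out_dir, "config.txt"))

  on.exit()  # success: keep outputs
  invisible(summary_df)
}
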