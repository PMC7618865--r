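#' Construct a residue chain
#'
#' A `residue_chain` is the toolkit's Calpha-level view of a single-chain
#' predicted structure: residue numbers, Calpha coordinates and the
#' per-residue plDDT confidence that AFDB-style models store in the
#' B-factor column.
#'
#' @param chain_id single chain identifier string.
#' @param residue_numbers strictly increasing integer vector of 1-based
#'   residue numbers.
#' @param ca_coords numeric matrix with one row per residue and columns
#'   x, y, z in Angstrom.
#' @param plddt numeric vector in `[0, 100]`, one value per residue.
#' @return an object of class `residue_chain`.
#' @export
residue_chain <- function(chain_id, residue_numbers, ca_coords, plddt) {
  residue_numbers <- as.integer(residue_numbers)
  ca_coords <- as.matrix(ca_coords)
  if (any(diff(residue_numbers) <= 0L))
    stop("residue_numbers must be strictly increasing")
  if (nrow(ca_coords) != length(residue_numbers) ||
      length(plddt) != length(residue_numbers))
    stop("ca_coords, plddt and residue_numbers must have equal length")
  if (ncol(ca_coords) != 3L) stop("ca_coords must be an n x 3 matrix")
  if (any(plddt < 0 | plddt > 100)) stop("plddt values must lie in [0, 100]")
  structure(list(chain_id = as.character(chain_id),
                 residue_numbers = residue_numbers,
                 ca_coords = unname(ca_coords),
                 plddt = as.numeric(plddt)),
            class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("<residue_chain %s: %d residues (%d-%d), mean plDDT %.1f>\n",
              x$chain_id, length(x$residue_numbers),
              min(x$residue_numbers), max(x$residue_numbers),
              mean(x$plddt)))
  invisible(x)
}

#' @export
length.residue_chain <- function(x) length(x$residue_numbers)

# Coordinates of a subset of residues (by residue number).
chain_coords <- function(chain, residues = NULL) {
  if (is.null(residues)) return(chain$ca_coords)
  idx <- match(residues, chain$residue_numbers)
  if (anyNA(idx))
    stop("residues not present in chain: ",
         paste(residues[is.na(idx)], collapse = ", "))
  chain$ca_coords[idx, , drop = FALSE]
}

#' Parse a chopping string
#'
#' A chopping partitions a chain's residues into domains. The string
#' dialect separates domains with `","` and the segments of a
#' discontinuous domain with `"_"`; every segment is an inclusive 1-based
#' range `"start-end"`. `"1-50_120-180,51-119"` is a two-domain chopping
#' whose first domain is discontinuous.
#'
#' @param text chopping string; `""` denotes a chopping with no domains.
#' @param source optional name of the segmentation method that produced it.
#' @return an object of class `chopping`: a list with `domains` (each a
#'   two-column `start`/`end` segment matrix) and `source`.
#' @export
parse_chopping <- function(text, source = "") {
  text <- trimws(text)
  if (!nzchar(text)) return(chopping(list(), source = source))
  dom_tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  domains <- lapply(dom_tokens, function(dtok) {
    seg_tokens <- strsplit(trimws(dtok), "_", fixed = TRUE)[[1]]
    segs <- t(vapply(seg_tokens, function(stok) {
      m <- regmatches(stok, regexec("^([0-9]+)-([0-9]+)$", trimws(stok)))[[1]]
      if (length(m) != 3L)
        stop("malformed segment token: '", stok, "'")
      rng <- as.integer(m[2:3])
      if (rng[1] > rng[2])
        stop("segment start exceeds end in '", stok, "'")
      rng
    }, integer(2)))
    colnames(segs) <- c("start", "end")
    segs[order(segs[, "start"]), , drop = FALSE]
  })
  chopping(domains, source = source)
}

#' Construct (and validate) a chopping
#'
#' @param domains list of segment matrices (columns `start`, `end`).
#' @param source method name.
#' @return a `chopping` object; errors if any residue is claimed by two
#'   domains or two segments.
#' @export
chopping <- function(domains, source = "") {
  domains <- lapply(domains, function(d) {
    d <- matrix(as.integer(d), ncol = 2, dimnames = list(NULL, c("start", "end")))
    d[order(d[, "start"]), , drop = FALSE]
  })
  seen <- integer(0)
  for (d in domains) {
    res <- unlist(lapply(seq_len(nrow(d)), function(i) seq.int(d[i, 1], d[i, 2])))
    dup <- c(res[duplicated(res)], intersect(res, seen))
    if (length(dup) > 0L)
      stop("residue ", dup[1], " assigned to more than one domain/segment")
    seen <- c(seen, res)
  }
  ord <- order(vapply(domains, function(d) if (nrow(d)) min(d[, "start"]) else NA_integer_,
                      integer(1)))
  structure(list(domains = domains[ord], source = as.character(source)),
            class = "chopping")
}

#' @export
print.chopping <- function(x, ...) {
  cat(sprintf("<chopping [%s]: %d domain(s) '%s'>\n", x$source,
              length(x$domains), format_chopping(x)))
  invisible(x)
}

#' Residue sets of a chopping
#'
#' @param chop a `chopping`.
#' @return list of sorted integer vectors, one per domain.
#' @export
chopping_residues <- function(chop) {
  lapply(chop$domains, residues_from_segments)
}

#' Format a chopping back to its string form
#'
#' Inverse of [parse_chopping()]: segments joined with `"_"`, domains with
#' `","`, domains ordered by first residue. Round-trips canonical strings.
#'
#' @param chop a `chopping`.
#' @return a chopping string (`""` for zero domains).
#' @export
format_chopping <- function(chop) {
  paste(vapply(chop$domains, function(d)
    paste(sprintf("%d-%d", d[, "start"], d[, "end"]), collapse = "_"),
    character(1)), collapse = ",")
}

#' Read a single-chain predicted structure
#'
#' Reads a PDB-format file at Calpha resolution. Per the AFDB convention
#' the per-residue plDDT is taken from the B-factor column; no separate
#' confidence file is supported.
#'
#' @param path path to a PDB file with a single chain.
#' @return a [residue_chain()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha records in ", path)
  chains <- unique(ca$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1L)
    stop("multi-chain input not supported (chains: ",
         paste(chains, collapse = ", "), ")")
  if (anyDuplicated(ca$resno))
    stop("duplicate residue number in ", path, ": ",
         ca$resno[duplicated(ca$resno)][1])
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  residue_chain(chain_id = if (length(chains)) chains else "A",
                residue_numbers = ca$resno,
                ca_coords = cbind(ca$x, ca$y, ca$z),
                plddt = ca$b)
}

#' Write a residue chain as a Calpha-only PDB file
#'
#' plDDT is stored in the B-factor column (AFDB convention).
#'
#' @param chain a [residue_chain()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(chain, path) {
  n <- length(chain$residue_numbers)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(chain$ca_coords)),
                   resno = chain$residue_numbers,
                   resid = rep("ALA", n),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep(substr(chain$chain_id, 1, 1), n),
                   o = rep(1, n),
                   b = chain$plddt)
  invisible(path)
}

#' Read a predicted aligned error matrix
#'
#' Accepts the AFDB JSON dialect: either a top-level object or a
#' one-element array holding a `predicted_aligned_error` field with an
#' n x n array of residue-pair errors in Angstrom.
#'
#' @param path path to a PAE JSON file.
#' @return an n x n numeric matrix of class `pae_matrix`.
#' @export
read_pae <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(obj)) obj <- as.list(obj)
  m <- obj[["predicted_aligned_error"]]
  if (is.null(m) && is.list(obj) && length(obj) >= 1L)
    m <- obj[[1]][["predicted_aligned_error"]]
  if (is.null(m)) stop("no predicted_aligned_error field in ", path)
  if (is.list(m) && !is.matrix(m)) {
    lens <- lengths(m)
    if (length(unique(lens)) != 1L) stop("ragged PAE rows in ", path)
    m <- do.call(rbind, m)
  }
  if (is.array(m) && length(dim(m)) == 3L) m <- m[1, , ]
  m <- unname(as.matrix(m))
  pae_matrix(m)
}

#' Construct and validate a PAE matrix
#'
#' @param values square numeric matrix of non-negative, finite errors (A).
#' @return the matrix with class `pae_matrix`.
#' @export
pae_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("PAE matrix must be square")
  if (any(!is.finite(values))) stop("PAE entries must be finite")
  if (any(values < 0)) stop("PAE entries must be non-negative")
  structure(unname(values), class = c("pae_matrix", "matrix", "array"))
}

#' Write a PAE matrix in the AFDB JSON dialect
#'
#' @param pae a `pae_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pae <- function(pae, path) {
  obj <- list(list(predicted_aligned_error = unclass(pae),
                   max_predicted_aligned_error = max(pae)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
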