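## Reading and sanitizing 3D RNA models; backbone and base-pair extraction.

BACKBONE_ATOMS <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
RNA_RESIDUES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                  "ADE", "CYT", "GUA", "URA", "URI")

## Canonical hydrogen-bonding atom patterns (donor/acceptor heavy atoms).
.pair_patterns <- list(
  "WC-AU" = list(bases = c("A", "U"),
                 atoms = list(c("N1", "N3"), c("N6", "O4"))),
  "WC-GC" = list(bases = c("G", "C"),
                 atoms = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2"))),
  "wobble-GU" = list(bases = c("G", "U"),
                     atoms = list(c("O6", "N3"), c("N1", "O2")))
)

normalize_base <- function(resid) {
  map <- c(A = "A", RA = "A", ADE = "A", C = "C", RC = "C", CYT = "C",
           G = "G", RG = "G", GUA = "G", U = "U", RU = "U", URA = "U",
           URI = "U")
  out <- unname(map[toupper(resid)])
  out[is.na(out)] <- "other"
  out
}

normalize_atom_name <- function(x) {
  x <- gsub("\\*", "'", trimws(x))
  x <- gsub("′", "'", x)
  x
}

## CASP TS submissions prepend free-text records that standard parsers may
## choke on; drop them before parsing.
strip_casp_headers <- function(lines) {
  drop <- grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|SCORE|PARENT|REMARK)", lines)
  lines[!drop]
}

#' Read a 3D RNA model from PDB or mmCIF
#'
#' Parses the file with bio3d, strips CASP TS header records and all
#' non-RNA residues (protein, heteroatoms, waters), and assembles the
#' retained RNA chains in file order. Multi-model files yield the first
#' model unless `model_index` says otherwise.
#'
#' @param path path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param model_index which MODEL block of a multi-model PDB to use.
#' @return an object of class `rna_model`: list with `model_id` (file stem),
#'   `chains` (named list; each chain has `chain_id`, a `residues` data frame
#'   with `number`, `icode`, `base`, and an `atoms` data frame with
#'   `residue`, `atom`, `x`, `y`, `z`), and `source_path`.
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif"),
                       model_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch({
    if (format == "mmcif") {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      lines <- readLines(path, warn = FALSE)
      clean <- strip_casp_headers(lines)
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp), add = TRUE)
      writeLines(clean, tmp)
      bio3d::read.pdb(tmp, multi = model_index > 1L, verbose = FALSE)
    }
  }, error = function(e) {
    stop("cannot parse '", path, "' as ", format, ": ",
         conditionMessage(e), call. = FALSE)
  })
  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model index ", model_index, " not present in ", path, call. = FALSE)
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$type == "ATOM" & toupper(trimws(at$resid)) %in% RNA_RESIDUES, ,
           drop = FALSE]
  if (!nrow(at))
    stop("no RNA residues in ", path, call. = FALSE)
  if (!all(is.finite(c(at$x, at$y, at$z))))
    stop("non-finite coordinates in ", path, call. = FALSE)
  at$elety <- normalize_atom_name(at$elety)
  at$insert[is.na(at$insert)] <- ""
  chains <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    key <- paste(sub$resno, sub$insert)
    ord <- order(sub$resno, sub$insert)
    sub <- sub[ord, , drop = FALSE]
    key <- paste(sub$resno, sub$insert)
    ukey <- unique(key)
    ridx <- match(key, ukey)
    first <- !duplicated(key)
    residues <- data.frame(number = sub$resno[first],
                           icode = sub$insert[first],
                           base = normalize_base(sub$resid[first]),
                           stringsAsFactors = FALSE)
    atoms <- data.frame(residue = ridx, atom = sub$elety,
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    cid <- if (is.na(ch) || ch == "") "A" else as.character(ch)
    chains[[cid]] <- structure(list(chain_id = cid, residues = residues,
                                    atoms = atoms),
                               class = "chain_record")
  }
  structure(list(model_id = tools::file_path_sans_ext(basename(path)),
                 chains = chains, source_path = path),
            class = "rna_model")
}

#' @export
print.rna_model <- function(x, ...) {
  cat("<rna_model>", x$model_id, "-", length(x$chains), "chain(s):",
      paste(vapply(x$chains, function(ch) paste0(ch$chain_id, "(",
                                                 nrow(ch$residues), " nt)"),
                   character(1)), collapse = ", "), "\n")
  invisible(x)
}

## All atom coordinates of a model as one data frame with chain column.
model_atoms <- function(model) {
  do.call(rbind, lapply(model$chains, function(ch) {
    cbind(chain = ch$chain_id, ch$atoms, stringsAsFactors = FALSE)
  }))
}

#' Find duplicated atom coordinates
#'
#' Predicted models occasionally place atoms of different residues on
#' identical coordinates; such models cannot be assessed for knots and are
#' flagged invalid. Returns every pair of atoms from distinct residues whose
#' coordinates are within `tolerance` of each other.
#'
#' @param model an `rna_model`.
#' @param tolerance distance in Angstrom below which two atoms count as
#'   duplicates.
#' @return data frame of offending pairs (chain/residue/atom of both sides
#'   and their distance); zero rows when the model is clean.
#' @export
detect_duplicate_coordinates <- function(model, tolerance = 0.01) {
  at <- model_atoms(model)
  n <- nrow(at)
  out <- data.frame()
  if (n < 2) return(out)
  cell <- max(tolerance, 1e-6)
  key <- paste(floor(at$x / cell), floor(at$y / cell), floor(at$z / cell))
  ## compare within each grid cell and its 26 neighbours via offset keys
  pairs <- list()
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ix <- floor(at$x / cell); iy <- floor(at$y / cell); iz <- floor(at$z / cell)
  bucket <- split(seq_len(n), paste(ix, iy, iz))
  for (o in seq_len(nrow(offs))) {
    shifted <- paste(ix + offs$dx[o], iy + offs$dy[o], iz + offs$dz[o])
    hit <- match(shifted, names(bucket))
    for (i in which(!is.na(hit))) {
      js <- bucket[[hit[i]]]
      js <- js[js > i]
      if (!length(js)) next
      d2 <- (at$x[js] - at$x[i])^2 + (at$y[js] - at$y[i])^2 +
        (at$z[js] - at$z[i])^2
      close <- js[d2 <= tolerance^2]
      distinct <- close[at$chain[close] != at$chain[i] |
                          at$residue[close] != at$residue[i]]
      if (length(distinct))
        pairs[[length(pairs) + 1L]] <- data.frame(
          i = i, j = distinct,
          dist = sqrt(d2[match(distinct, js)]))
    }
  }
  if (!length(pairs)) return(out)
  pr <- unique(do.call(rbind, pairs))
  data.frame(chain_a = at$chain[pr$i], residue_a = at$residue[pr$i],
             atom_a = at$atom[pr$i],
             chain_b = at$chain[pr$j], residue_b = at$residue[pr$j],
             atom_b = at$atom[pr$j], dist = pr$dist,
             stringsAsFactors = FALSE)
}

#' Extract the sugar-phosphate backbone polyline of a chain
#'
#' Appends, per residue, the six backbone atoms P, O5', C5', C4', C3', O3'
#' in that fixed order. A missing P on the first residue (the usual 5'
#' convention) is tolerated; any other missing backbone atom causes the
#' residue to be skipped with a warning.
#'
#' @param model an `rna_model`.
#' @param chain_id chain identifier; defaults to the first chain.
#' @return object of class `backbone_chain`: `chain_id`, `points`
#'   (`n x 3` matrix), `residue_of_point` (integer residue index per point).
#' @export
extract_backbone <- function(model, chain_id = NULL) {
  if (is.null(chain_id)) chain_id <- names(model$chains)[1]
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("no chain '", chain_id, "' in model ",
                        model$model_id, call. = FALSE)
  pts <- list()
  rix <- integer(0)
  skipped <- integer(0)
  nres <- nrow(ch$residues)
  for (r in seq_len(nres)) {
    sub <- ch$atoms[ch$atoms$residue == r, , drop = FALSE]
    m <- match(BACKBONE_ATOMS, sub$atom)
    need <- if (r == 1L) m[-1] else m
    if (anyNA(need)) {
      skipped <- c(skipped, r)
      next
    }
    m <- m[!is.na(m)]
    pts[[length(pts) + 1L]] <- as.matrix(sub[m, c("x", "y", "z")])
    rix <- c(rix, rep(r, length(m)))
  }
  if (length(skipped))
    warning("chain ", chain_id, ": skipped ", length(skipped),
            " residue(s) with incomplete backbone (",
            paste(utils::head(skipped, 5), collapse = ","),
            if (length(skipped) > 5) ",..." else "", ")", call. = FALSE)
  if (length(pts) < 3)
    stop("chain ", chain_id, ": fewer than 3 usable residues", call. = FALSE)
  P <- do.call(rbind, pts)
  dimnames(P) <- NULL
  keep <- c(TRUE, rowSums((P[-1, , drop = FALSE] -
                             P[-nrow(P), , drop = FALSE])^2) > 1e-18)
  structure(list(chain_id = chain_id, points = P[keep, , drop = FALSE],
                 residue_of_point = rix[keep]),
            class = "backbone_chain")
}

#' Annotate canonical base pairs of a chain
#'
#' Either detects canonical pairs (Watson-Crick A-U/G-C and wobble G-U)
#' geometrically, or ingests a layered dot-bracket string. Detection accepts
#' a pair when the C1'-C1' distance is in 10-11 A and every donor-acceptor
#' heavy-atom distance of the canonical pattern is in 2.4-3.5 A; each residue
#' keeps its best-scoring partner. Pairs are assigned to pseudoknot layers so
#' that each layer is crossing-free.
#'
#' @param model an `rna_model`.
#' @param source `"detect"` or `"dotbracket"`.
#' @param dotbracket layered dot-bracket string (`()[]{}<>`), required when
#'   `source = "dotbracket"`; its length must equal the chain's residue count.
#' @param chain_id chain to annotate; defaults to the first chain.
#' @return object of class `secondary_structure`: `pairs` data frame with
#'   `i`, `j` (residue indices, `i < j`), `pair_class`, `layer`; plus
#'   `n_residues` and `chain_id`.
#' @export
annotate_base_pairs <- function(model, source = c("detect", "dotbracket"),
                                dotbracket = NULL, chain_id = NULL) {
  source <- match.arg(source)
  if (is.null(chain_id)) chain_id <- names(model$chains)[1]
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("no chain '", chain_id, "'", call. = FALSE)
  n <- nrow(ch$residues)
  if (source == "dotbracket") {
    if (is.null(dotbracket)) stop("dotbracket string required", call. = FALSE)
    if (nchar(dotbracket) != n)
      stop("dot-bracket length ", nchar(dotbracket),
           " does not match residue count ", n, call. = FALSE)
    pairs <- parse_dotbracket(dotbracket)
    if (nrow(pairs)) {
      b <- ch$residues$base
      pairs$pair_class <- pair_class_of(b[pairs$i], b[pairs$j])
    }
  } else {
    pairs <- detect_pairs_geometric(ch)
  }
  structure(list(pairs = pairs, n_residues = n, chain_id = chain_id),
            class = "secondary_structure")
}

pair_class_of <- function(bi, bj) {
  key <- paste(pmin(bi, bj), pmax(bi, bj))
  out <- rep("other", length(key))
  out[key == "A U"] <- "WC-AU"
  out[key == "C G"] <- "WC-GC"
  out[key == "G U"] <- "wobble-GU"
  out
}

#' Parse a layered dot-bracket string
#'
#' Bracket alphabets `()`, `[]`, `{}`, `<>` encode pseudoknot layers 1-4.
#'
#' @param db dot-bracket string.
#' @return data frame with columns `i`, `j`, `layer`.
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  opens <- c("(", "[", "{", "<")
  closes <- c(")", "]", "}", ">")
  known <- c(opens, closes, ".", "-")
  if (any(!chars %in% known))
    stop("unsupported dot-bracket character: ",
         paste(unique(chars[!chars %in% known]), collapse = ""), call. = FALSE)
  out <- list()
  for (layer in seq_along(opens)) {
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == opens[layer]) {
        stack <- c(stack, k)
      } else if (chars[k] == closes[layer]) {
        if (!length(stack))
          stop("unbalanced dot-bracket: unmatched '", closes[layer],
               "' at position ", k, call. = FALSE)
        out[[length(out) + 1L]] <- c(stack[length(stack)], k, layer)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced dot-bracket: unmatched '", opens[layer], "'",
           call. = FALSE)
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      layer = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(i = m[, 1], j = m[, 2], layer = m[, 3])
  df[order(df$i), , drop = FALSE]
}

#' Serialize base pairs to a layered dot-bracket string
#'
#' @param ss a `secondary_structure`.
#' @return a dot-bracket string with one bracket alphabet per layer.
#' @export
write_dotbracket <- function(ss) {
  opens <- c("(", "[", "{", "<")
  closes <- c(")", "]", "}", ">")
  chars <- rep(".", ss$n_residues)
  p <- ss$pairs
  for (k in seq_len(nrow(p))) {
    l <- p$layer[k]
    if (l > length(opens)) stop("more pseudoknot layers than bracket types")
    chars[p$i[k]] <- opens[l]
    chars[p$j[k]] <- closes[l]
  }
  paste(chars, collapse = "")
}

## Geometric canonical-pair detection on one chain.
detect_pairs_geometric <- function(ch, c1_range = c(10, 11),
                                   hb_range = c(2.4, 3.5)) {
  n <- nrow(ch$residues)
  at <- ch$atoms
  coord_of <- function(r, name) {
    hit <- which(at$residue == r & at$atom == name)
    if (!length(hit)) return(NULL)
    c(at$x[hit[1]], at$y[hit[1]], at$z[hit[1]])
  }
  c1 <- t(vapply(seq_len(n), function(r) {
    p <- coord_of(r, "C1'")
    if (is.null(p)) rep(NA_real_, 3) else p
  }, numeric(3)))
  cand <- list()
  for (i in seq_len(n)) {
    if (anyNA(c1[i, ])) next
    for (j in seq_len(n)) {
      if (j <= i + 2) next
      if (anyNA(c1[j, ])) next
      d <- sqrt(sum((c1[i, ] - c1[j, ])^2))
      if (d < c1_range[1] || d > c1_range[2]) next
      hit <- match_pair_pattern(ch, i, j, coord_of, hb_range)
      if (!is.null(hit))
        cand[[length(cand) + 1L]] <- data.frame(i = i, j = j,
                                                pair_class = hit$class,
                                                score = hit$score)
    }
  }
  if (!length(cand))
    return(data.frame(i = integer(0), j = integer(0),
                      pair_class = character(0), layer = integer(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$score), , drop = FALSE]
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      keep[k] <- TRUE
      used[cand$i[k]] <- TRUE
      used[cand$j[k]] <- TRUE
    }
  }
  pairs <- cand[keep, c("i", "j", "pair_class"), drop = FALSE]
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  pairs$layer <- assign_pk_layers(pairs)
  rownames(pairs) <- NULL
  pairs
}

## Try canonical patterns in both orientations; return best (lowest score).
match_pair_pattern <- function(ch, i, j, coord_of, hb_range) {
  bi <- ch$residues$base[i]
  bj <- ch$residues$base[j]
  best <- NULL
  for (cls in names(.pair_patterns)) {
    pat <- .pair_patterns[[cls]]
    for (orient in 1:2) {
      a <- if (orient == 1) c(bi, i) else c(bj, j)
      b <- if (orient == 1) c(bj, j) else c(bi, i)
      if (a[1] != pat$bases[1] || b[1] != pat$bases[2]) next
      ds <- numeric(0)
      ok <- TRUE
      for (bond in pat$atoms) {
        pa <- coord_of(as.integer(a[2]), bond[1])
        pb <- coord_of(as.integer(b[2]), bond[2])
        if (is.null(pa) || is.null(pb)) { ok <- FALSE; break }
        d <- sqrt(sum((pa - pb)^2))
        if (d < hb_range[1] || d > hb_range[2]) { ok <- FALSE; break }
        ds <- c(ds, d)
      }
      if (!ok) next
      score <- mean(abs(ds - 2.9))
      if (is.null(best) || score < best$score)
        best <- list(class = cls, score = score)
    }
  }
  best
}

## Greedy pseudoknot layering: each layer is a maximal crossing-free subset.
assign_pk_layers <- function(pairs) {
  np <- nrow(pairs)
  if (!np) return(integer(0))
  layer <- rep(NA_integer_, np)
  l <- 0L
  while (anyNA(layer)) {
    l <- l + 1L
    sel <- integer(0)
    for (k in order(pairs$i)) {
      if (!is.na(layer[k])) next
      crosses <- any(vapply(sel, function(s) {
        (pairs$i[s] < pairs$i[k] & pairs$i[k] < pairs$j[s] &
           pairs$j[s] < pairs$j[k]) |
          (pairs$i[k] < pairs$i[s] & pairs$i[s] < pairs$j[k] &
             pairs$j[k] < pairs$j[s])
      }, logical(1)))
      if (!crosses) {
        layer[k] <- l
        sel <- c(sel, k)
      }
    }
  }
  layer
}
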