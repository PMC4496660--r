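# Independent brute-force oracles used by the property tests. These work
# directly off the raw edge tables (own union-find, own DFS / substitution
# enumeration) so they share no traversal code with the implementation.

# All-simple-chain enumeration for path weight/distance: collapse synonym
# classes by repeated merging, build undirected weighted adjacency from the
# subclass/group tables, enumerate every simple path, pick minimum edge
# count then maximum weight product.
oracle_path <- function(graph, a, z) {
  ids <- graph$concepts$id
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(graph$synonym)) {
    for (i in seq_len(nrow(graph$synonym))) {
      ra <- find(graph$synonym$a[i])
      rb <- find(graph$synonym$b[i])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  rep_of <- vapply(ids, find, character(1))

  edges <- list()
  add_edge <- function(p, c_, w) {
    edges[[length(edges) + 1]] <<- list(p = p, c = c_, w = w)
  }
  if (nrow(graph$subclass)) {
    sp <- unique(data.frame(p = unname(rep_of[graph$subclass$parent]),
                            c = unname(rep_of[graph$subclass$child])))
    sp <- sp[sp$p != sp$c, , drop = FALSE]
    for (p in unique(sp$p)) {
      kids <- sp$c[sp$p == p]
      for (k in kids) {
        w <- 1 / length(kids)
        ov <- graph$weight_overrides
        if (nrow(ov)) {
          hit <- which(unname(rep_of[ov$parent]) == p &
                         unname(rep_of[ov$child]) == k)
          if (length(hit)) w <- ov$weight[hit[1]]
        }
        add_edge(p, k, w)
      }
    }
  }
  if (nrow(graph$group)) {
    gp <- unique(data.frame(p = unname(rep_of[graph$group$group]),
                            c = unname(rep_of[graph$group$member])))
    gp <- gp[gp$p != gp$c, , drop = FALSE]
    for (p in unique(gp$p)) {
      kids <- gp$c[gp$p == p]
      for (k in kids) add_edge(p, k, 1 / length(kids))
    }
  }

  ra <- rep_of[[normalize_term(a)]]
  rz <- rep_of[[normalize_term(z)]]
  if (normalize_term(a) == normalize_term(z)) {
    return(list(weight = 1, distance = 0L))
  }
  if (ra == rz) return(list(weight = 1, distance = 1L))

  best <- NULL
  walk <- function(node, visited, dist, wprod) {
    if (node == rz) {
      if (is.null(best) || dist < best$distance ||
          (dist == best$distance && wprod > best$weight)) {
        best <<- list(weight = wprod, distance = dist)
      }
      return()
    }
    for (e in edges) {
      nxt <- NULL
      if (e$p == node && !(e$c %in% visited)) nxt <- e$c
      if (e$c == node && !(e$p %in% visited)) nxt <- e$p
      if (!is.null(nxt)) walk(nxt, c(visited, nxt), dist + 1L, wprod * e$w)
    }
  }
  walk(ra, ra, 0L, 1)
  best
}

# Naive rule saturation: enumerate every substitution of body variables over
# the named individuals, check each instantiated atom against the fact table,
# assert heads; repeat until nothing new.
oracle_saturate <- function(facts, rules) {
  df <- as.data.frame(facts)
  has_fact <- function(pred, a1, a2) {
    rows <- df[df$predicate == pred & df$arg1 == a1, , drop = FALSE]
    if (is.na(a2)) any(is.na(rows$arg2)) else any(!is.na(rows$arg2) &
                                                    rows$arg2 == a2)
  }
  repeat {
    inds <- unique(c(df$arg1, df$arg2))
    inds <- inds[!is.na(inds)]
    added <- FALSE
    for (rule in rules) {
      vars <- unique(unlist(lapply(rule$body, function(a)
        a$args[a$is_var & !a$builtin])))
      grids <- if (length(vars)) {
        expand.grid(rep(list(inds), length(vars)),
                    stringsAsFactors = FALSE)
      } else {
        data.frame(row.names = 1)
      }
      for (r in seq_len(nrow(grids))) {
        b <- if (length(vars)) stats::setNames(as.character(grids[r, ]),
                                               vars) else character()
        ok <- TRUE
        for (atom in rule$body) {
          args <- ifelse(atom$is_var, unname(b[atom$args]), atom$args)
          if (atom$builtin) {
            nums <- suppressWarnings(as.numeric(args))
            if (anyNA(nums)) { ok <- FALSE; break }
            pass <- if (atom$predicate == "greaterthan") nums[1] > nums[2]
              else nums[1] < nums[2]
            if (!pass) { ok <- FALSE; break }
          } else {
            a2 <- if (length(args) == 2) args[2] else NA_character_
            if (!has_fact(atom$predicate, args[1], a2)) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        for (atom in rule$head) {
          args <- ifelse(atom$is_var, unname(b[atom$args]), atom$args)
          a2 <- if (length(args) == 2) args[2] else NA_character_
          if (!has_fact(atom$predicate, args[1], a2)) {
            df <- rbind(df, data.frame(predicate = atom$predicate,
                                       arg1 = args[1], arg2 = a2,
                                       stringsAsFactors = FALSE))
            added <- TRUE
          }
        }
      }
    }
    if (!added) break
  }
  rownames(df) <- NULL
  df
}

# Canonical comparable form of a fact table
fact_key <- function(df) {
  sort(paste(df$predicate, df$arg1, ifelse(is.na(df$arg2), "", df$arg2)))
}

# Random small fact base + rules for chaining property tests
random_fact_base <- function(seed) {
  set.seed(seed)
  inds <- paste0("i", 1:5)
  n <- sample(3:8, 1)
  fact_base(
    predicate = sample(c("A", "P", "Q"), n, replace = TRUE),
    arg1 = sample(inds, n, replace = TRUE),
    arg2 = ifelse(runif(n) < 0.5, NA_character_,
                  sample(inds, n, replace = TRUE)))
}

chain_rules <- list(
  parse_rule("A(?x) -> B(?x)"),
  parse_rule("B(?x) -> C(?x)"),
  parse_rule("P(?x, ?y), Q(?y, ?z) -> R(?x, ?z)"))

# Graph content comparison helper (edge sets as sets, labels ignored)
expect_same_graph <- function(g1, g2) {
  pair_key <- function(df) sort(paste(df[[1]], df[[2]])) # nolint
  expect_setequal(g1$concepts$id, g2$concepts$id)
  expect_identical(pair_key(g1$subclass), pair_key(g2$subclass))
  # synonym edges are undirected: compare orientation-free
  syn_key <- function(df) sort(paste(pmin(df$a, df$b), pmax(df$a, df$b)))
  expect_identical(syn_key(g1$synonym), syn_key(g2$synonym))
  expect_identical(pair_key(g1$group), pair_key(g2$group))
}
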