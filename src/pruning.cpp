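#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Felsenstein pruning over the 61 sense-codon states of a branch-category
// codon model, with optional analytic derivatives of the log-likelihood
// with respect to every branch length.
//
// edge      E x 2 (parent, child), 1-based node ids, rows in postorder
//           (every edge below a node precedes the edge above it);
//           tips are nodes 1..ntip.
// edge_len  E branch lengths (expected substitutions per codon).
// edge_cat  E 1-based branch-category index.
// A, B      61 x 61 x C spectral factors per category, lambda 61 x C:
//           P(t) = A * diag(exp(lambda * t)) * B.
// tips      ntip x S integer codon states (1..61), 0 = fully ambiguous
//           (gap / N / ? / stop-recorded-as-missing).
// weights   S site-pattern weights.
// pi        61 root (equilibrium) frequencies.
//
// Site likelihoods are rescaled per node by their column maxima to avoid
// underflow; the scalers cancel exactly in the gradient ratios.

// [[Rcpp::export]]
Rcpp::List pruning_loglik(const arma::imat& edge,
                          const arma::vec& edge_len,
                          const arma::ivec& edge_cat,
                          const arma::cube& A,
                          const arma::cube& B,
                          const arma::mat& lambda,
                          const arma::imat& tips,
                          const arma::vec& weights,
                          const arma::vec& pi,
                          const int nnode,
                          const bool want_grad) {
  const int ntip = tips.n_rows;
  const int S = tips.n_cols;
  const int E = edge.n_rows;
  const int N = ntip + nnode;

  // per-edge transition matrices
  cube P(61, 61, E);
  for (int e = 0; e < E; ++e) {
    const int c = edge_cat(e) - 1;
    P.slice(e) = A.slice(c) * diagmat(exp(lambda.col(c) * edge_len(e))) *
                 B.slice(c);
  }

  // node partials and per-node accumulated log-scalers
  cube L(61, S, N);
  mat logsc(S, N, fill::zeros);
  for (int i = 0; i < ntip; ++i) {
    L.slice(i).zeros();
    for (int s = 0; s < S; ++s) {
      const int st = tips(i, s);
      if (st == 0)
        L.slice(i).col(s).ones();
      else
        L(st - 1, s, i) = 1.0;
    }
  }
  for (int i = ntip; i < N; ++i) L.slice(i).ones();

  std::vector<std::vector<int>> child_edges(N);
  std::vector<int> parent_edge(N, -1);
  for (int e = 0; e < E; ++e) {
    child_edges[edge(e, 0) - 1].push_back(e);
    parent_edge[edge(e, 1) - 1] = e;
  }

  cube Ce(61, S, E);    // scaled per-edge contributions P_e L_child / m_e
  mat  Me(E, S);        // the scalers m_e
  bool underflow = false;

  for (int e = 0; e < E; ++e) {
    const int p = edge(e, 0) - 1;
    const int c = edge(e, 1) - 1;
    mat con = P.slice(e) * L.slice(c);
    rowvec m = max(con, 0);
    for (int s = 0; s < S; ++s) {
      if (m(s) <= 0) { m(s) = 1.0; underflow = true; }
    }
    con.each_row() /= m;
    Ce.slice(e) = con;
    Me.row(e) = m;
    L.slice(p) %= con;
    logsc.col(p) += logsc.col(c) + log(m).t();
  }

  const int root = edge(E - 1, 0) - 1;
  rowvec v = pi.t() * L.slice(root);
  vec sitell(S);
  for (int s = 0; s < S; ++s)
    sitell(s) = (v(s) > 0 ? std::log(v(s)) : -datum::inf) + logsc(s, root);
  const double ll = dot(weights, sitell);

  vec grad;
  if (want_grad && std::isfinite(ll) && !underflow) {
    grad.set_size(E);
    for (int e = 0; e < E; ++e) {
      const int c0 = edge_cat(e) - 1;
      const int ch = edge(e, 1) - 1;
      mat dP = A.slice(c0) *
               diagmat(lambda.col(c0) % exp(lambda.col(c0) * edge_len(e))) *
               B.slice(c0);
      mat cur = dP * L.slice(ch);
      cur.each_row() /= Me.row(e);
      int eidx = e;
      int node = edge(e, 0) - 1;
      while (parent_edge[node] >= 0) {
        // partial at `node` with edge eidx's contribution replaced
        mat part(61, S, fill::ones);
        for (int e2 : child_edges[node])
          part %= (e2 == eidx ? cur : Ce.slice(e2));
        const int eu = parent_edge[node];
        cur = P.slice(eu) * part;
        cur.each_row() /= Me.row(eu);
        eidx = eu;
        node = edge(eu, 0) - 1;
      }
      mat part(61, S, fill::ones);
      for (int e2 : child_edges[root])
        part %= (e2 == eidx ? cur : Ce.slice(e2));
      rowvec dv = pi.t() * part;
      double g = 0.0;
      for (int s = 0; s < S; ++s) g += weights(s) * dv(s) / v(s);
      grad(e) = g;
    }
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("site_loglik") = sitell,
                            Rcpp::Named("grad") = grad);
}

// Affine-gap global alignment of two profiles given a precomputed
// column-pair score matrix S (n1 x n2). Returns the aligned column index
// vectors (0 marks a gap). Gotoh three-state DP; ties prefer match, then
// gap in the second profile.
// [[Rcpp::export]]
Rcpp::List profile_align(const arma::mat& S, const double gap_open,
                         const double gap_ext) {
  const int n = S.n_rows, m = S.n_cols;
  const double NEG = -1e300;
  mat M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  imat tbM(n + 1, m + 1, fill::zeros), tbX(n + 1, m + 1, fill::zeros),
       tbY(n + 1, m + 1, fill::zeros);
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  M(0, 0) = 0;
  for (int i = 1; i <= n; ++i) {   // X: gap in profile 2 (consume profile 1)
    X(i, 0) = -gap_open - gap_ext * (i - 1);
    tbX(i, 0) = (i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= m; ++j) {
    Y(0, j) = -gap_open - gap_ext * (j - 1);
    tbY(0, j) = (j == 1 ? 0 : 2);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(i - 1, j - 1);
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      if (a >= b && a >= c) { M(i, j) = a + s; tbM(i, j) = 0; }
      else if (b >= c)      { M(i, j) = b + s; tbM(i, j) = 1; }
      else                  { M(i, j) = c + s; tbM(i, j) = 2; }
      a = M(i - 1, j) - gap_open; b = X(i - 1, j) - gap_ext;
      if (a >= b) { X(i, j) = a; tbX(i, j) = 0; }
      else        { X(i, j) = b; tbX(i, j) = 1; }
      a = M(i, j - 1) - gap_open; c = Y(i, j - 1) - gap_ext;
      if (a >= c) { Y(i, j) = a; tbY(i, j) = 0; }
      else        { Y(i, j) = c; tbY(i, j) = 2; }
    }
  }
  int state;
  double best = M(n, m); state = 0;
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  std::vector<int> ai, aj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      ai.push_back(i); aj.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      ai.push_back(i); aj.push_back(0); --i; state = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); aj.push_back(j); --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(aj.begin(), aj.end());
  return Rcpp::List::create(Rcpp::Named("i") = ai, Rcpp::Named("j") = aj,
                            Rcpp::Named("score") = best);
}
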