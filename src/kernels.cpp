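// Low-level numerical kernels. All matrices of Mueller images arrive as
// n x 16 row blocks in element order m11, m12, ..., m44 (pixel-major).
#include <RcppArmadillo.h>
#include <functional>
#include <unordered_set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 2D convolution with reflect padding (kernel normalized by caller).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat conv_sep_reflect_cpp(const arma::mat& img, const arma::vec& kernel) {
  const int h = img.n_rows, w = img.n_cols;
  const int r = (kernel.n_elem - 1) / 2;
  auto reflect = [](int i, int n) {
    // reflect without repeating the edge sample (scipy 'mirror' uses no repeat;
    // numpy 'reflect' repeats). We repeat the edge: ... 1 0 | 0 1 ...
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };
  arma::mat tmp(h, w), out(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t)
        s += kernel[t + r] * img(reflect(i + t, h), j);
      tmp(i, j) = s;
    }
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t)
        s += kernel[t + r] * tmp(i, reflect(j + t, w));
      out(i, j) = s;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Pauli-basis coherency transform and Cloude eigenvalue filter.
// ---------------------------------------------------------------------------

static std::vector<arma::cx_mat> pauli_basis() {
  using cx = std::complex<double>;
  arma::cx_mat s0(2, 2, arma::fill::zeros), s1 = s0, s2 = s0, s3 = s0;
  s0(0, 0) = 1; s0(1, 1) = 1;
  s1(0, 0) = 1; s1(1, 1) = -1;
  s2(0, 1) = 1; s2(1, 0) = 1;
  s3(0, 1) = cx(0, -1); s3(1, 0) = cx(0, 1);
  std::vector<arma::cx_mat> sig{s0, s1, s2, s3};
  std::vector<arma::cx_mat> B;
  B.reserve(16);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      B.push_back(arma::kron(sig[i], arma::conj(sig[j])));
  return B;
}

// Filter a block of Mueller matrices: clamp coherency eigenvalues below
// eig_floor, reconstruct, rescale trace back to the original m11.
// Returns filtered block, the pre-filter minimum eigenvalue, and validity.
// [[Rcpp::export]]
List cloude_filter_block_cpp(const arma::mat& M, double eig_floor) {
  static const std::vector<arma::cx_mat> B = pauli_basis();
  const int n = M.n_rows;
  arma::mat out(n, 16);
  arma::vec min_eig(n);
  LogicalVector valid(n);
  for (int p = 0; p < n; ++p) {
    double m11 = M(p, 0);
    if (!(m11 > 0) || !arma::is_finite(M.row(p))) {
      out.row(p) = M.row(p);
      min_eig[p] = NA_REAL;
      valid[p] = false;
      continue;
    }
    arma::cx_mat H(4, 4, arma::fill::zeros);
    for (int c = 0; c < 16; ++c) H += 0.25 * M(p, c) * B[c];
    H = 0.5 * (H + H.t());
    arma::vec ev;
    arma::cx_mat V;
    arma::eig_sym(ev, V, H);
    min_eig[p] = ev.min();
    valid[p] = true;
    if (ev.min() >= eig_floor) {
      out.row(p) = M.row(p);
      continue;
    }
    arma::vec evc = arma::clamp(ev, eig_floor, arma::datum::inf);
    arma::cx_mat H2 = V * arma::diagmat(arma::conv_to<arma::cx_vec>::from(evc)) * V.t();
    double tr = arma::trace(H2).real();
    if (tr > 0) H2 *= m11 / tr;
    for (int c = 0; c < 16; ++c)
      out(p, c) = arma::trace(H2 * B[c]).real();
  }
  return List::create(_["M"] = out, _["min_eig"] = min_eig, _["valid"] = valid);
}

// Minimum coherency eigenvalue per pixel (physicality diagnostic).
// [[Rcpp::export]]
arma::vec coherency_min_eig_cpp(const arma::mat& M) {
  static const std::vector<arma::cx_mat> B = pauli_basis();
  const int n = M.n_rows;
  arma::vec out(n);
  for (int p = 0; p < n; ++p) {
    if (!arma::is_finite(M.row(p))) { out[p] = NA_REAL; continue; }
    arma::cx_mat H(4, 4, arma::fill::zeros);
    for (int c = 0; c < 16; ++c) H += 0.25 * M(p, c) * B[c];
    H = 0.5 * (H + H.t());
    out[p] = arma::eig_sym(H).min();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lu-Chipman polar decomposition over a block of Mueller matrices.
// Output columns: D, Delta, R_tot, delta_lin, psi, theta.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat mmpd_block_cpp(const arma::mat& M) {
  const int n = M.n_rows;
  arma::mat out(n, 6);
  out.fill(NA_REAL);
  const double pi = arma::datum::pi;
  for (int p = 0; p < n; ++p) {
    double m11 = M(p, 0);
    if (!(m11 > 0) || !arma::is_finite(M.row(p))) continue;
    arma::mat Mn(4, 4);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) Mn(i, j) = M(p, i * 4 + j) / m11;
    arma::vec Dv = {Mn(0, 1), Mn(0, 2), Mn(0, 3)};
    double D = arma::norm(Dv);
    out(p, 0) = std::min(D, 1.0);
    if (D >= 1.0 - 1e-9) continue;  // retarder/depolarizer undefined
    double q = std::sqrt(1.0 - D * D);
    arma::mat mD3 = q * arma::eye(3, 3);
    if (D > 0) {
      arma::vec Dh = Dv / D;
      mD3 += (1.0 - q) * (Dh * Dh.t());
    }
    arma::mat MD(4, 4, arma::fill::zeros);
    MD(0, 0) = 1.0;
    MD.submat(0, 1, 0, 3) = Dv.t();
    MD.submat(1, 0, 3, 0) = Dv;
    MD.submat(1, 1, 3, 3) = mD3;
    arma::mat Mp = Mn * arma::inv(MD);
    arma::mat mp = Mp.submat(1, 1, 3, 3);
    arma::mat S = mp * mp.t();
    arma::vec ev;
    arma::mat V;
    arma::eig_sym(ev, V, S);
    ev = arma::clamp(ev, 0.0, arma::datum::inf);
    arma::mat sq = V * arma::diagmat(arma::sqrt(ev)) * V.t();
    double s = (arma::det(mp) < 0) ? -1.0 : 1.0;
    arma::mat mDelta = s * sq;
    out(p, 1) = 1.0 - std::abs(arma::trace(mDelta)) / 3.0;  // Delta
    arma::mat mR;
    bool ok = arma::solve(mR, mDelta, mp, arma::solve_opts::no_approx);
    if (!ok) {
      arma::mat mDinv = arma::pinv(mDelta);
      mR = mDinv * mp;
    }
    double ctot = ((1.0 + arma::trace(mR)) / 2.0) - 1.0;
    out(p, 2) = std::acos(std::min(1.0, std::max(-1.0, ctot)));
    double clin = std::sqrt(std::pow(mR(0, 0) + mR(1, 1), 2) +
                            std::pow(mR(1, 0) - mR(0, 1), 2)) - 1.0;
    out(p, 3) = std::acos(std::min(1.0, std::max(-1.0, clin)));
    out(p, 4) = 0.5 * std::atan2(mR(1, 0) - mR(0, 1), mR(0, 0) + mR(1, 1));
    double r1 = mR(1, 2) - mR(2, 1);  // horizontal linear retardance component
    double r2 = mR(2, 0) - mR(0, 2);  // 45-degree component
    double th = 0.5 * std::atan2(r2, r1);
    th -= pi * std::floor(th / pi);  // reduce to [0, pi)
    if (th >= pi) th = 0.0;
    out(p, 5) = th;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force k nearest neighbours under the Canberra distance
// sum_i |x_i - y_i| / (|x_i| + |y_i|), 0/0 terms contributing 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List knn_canberra_cpp(const arma::mat& X, const arma::mat& Q, int k) {
  const int n = X.n_rows, m = Q.n_rows, d = X.n_cols;
  if (k > n) stop("k exceeds the number of reference rows");
  arma::imat idx(m, k);
  arma::mat dist(m, k);
  std::vector<std::pair<double, int>> cand(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double num = std::abs(Q(i, c) - X(j, c));
        double den = std::abs(Q(i, c)) + std::abs(X(j, c));
        if (den > 0) s += num / den;
      }
      cand[j] = {s, j};
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int t = 0; t < k; ++t) {
      idx(i, t) = cand[t].second + 1;
      dist(i, t) = cand[t].first;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// [[Rcpp::export]]
double canberra_cpp(const arma::vec& x, const arma::vec& y) {
  if (x.n_elem != y.n_elem) stop("length mismatch");
  double s = 0.0;
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double den = std::abs(x[i]) + std::abs(y[i]);
    if (den > 0) s += std::abs(x[i] - y[i]) / den;
  }
  return s;
}

// ---------------------------------------------------------------------------
// Minibatch k-means with k-means++ initialisation. Uses R's RNG so results
// are reproducible under set.seed(). Returns final full-data assignment.
// ---------------------------------------------------------------------------

static arma::uvec sample_without_replacement(int n, int m) {
  // Floyd's algorithm on R's RNG
  std::unordered_set<int> chosen;
  arma::uvec out(m);
  int t = 0;
  for (int j = n - m; j < n; ++j) {
    int r = static_cast<int>(R::unif_rand() * (j + 1));
    if (r > j) r = j;
    if (chosen.count(r)) r = j;
    chosen.insert(r);
    out[t++] = r;
  }
  return out;
}

static void assign_block(const arma::mat& X, const arma::mat& C,
                         arma::uvec& assign, arma::vec& mind) {
  // squared Euclidean; ties go to the lowest centre index (stable argmin)
  arma::vec cn = arma::sum(arma::square(C), 1);
  const int n = X.n_rows;
  const int block = 8192;
  assign.set_size(n);
  mind.set_size(n);
  for (int s = 0; s < n; s += block) {
    int e = std::min(n, s + block);
    arma::mat Xi = X.rows(s, e - 1);
    arma::mat G = Xi * C.t();
    G.each_row() -= 0.5 * cn.t();
    for (int i = 0; i < e - s; ++i) {
      arma::uword j = G.row(i).index_max();  // first maximum -> lowest index on ties
      assign[s + i] = j;
      double xn = arma::dot(Xi.row(i), Xi.row(i));
      // G(i,j) = x.c - |c|^2/2, so |x-c|^2 = |x|^2 - 2 G(i,j)
      mind[s + i] = std::max(0.0, xn - 2.0 * G(i, j));
    }
  }
}

static arma::mat kmeanspp_init(const arma::mat& X, int k) {
  const int n = X.n_rows;
  arma::mat C(k, X.n_cols);
  arma::vec xn = arma::sum(arma::square(X), 1);
  int first = static_cast<int>(R::unif_rand() * n);
  if (first >= n) first = n - 1;
  C.row(0) = X.row(first);
  arma::vec d0 = xn - 2.0 * (X * C.row(0).t()) + arma::dot(C.row(0), C.row(0));
  arma::vec mind = arma::clamp(d0, 0.0, arma::datum::inf);
  for (int c = 1; c < k; ++c) {
    double tot = arma::accu(mind);
    int pick;
    if (tot <= 0) {
      pick = static_cast<int>(R::unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = R::unif_rand() * tot, acc = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += mind[i];
        if (acc >= u) { pick = i; break; }
      }
    }
    C.row(c) = X.row(pick);
    arma::vec d = xn - 2.0 * (X * C.row(c).t()) + arma::dot(C.row(c), C.row(c));
    mind = arma::min(mind, arma::clamp(d, 0.0, arma::datum::inf));
  }
  return C;
}

// [[Rcpp::export]]
List minibatch_kmeans_cpp(const arma::mat& X, int k, int batch_size,
                          int n_init, int max_iter, double tol,
                          int init_subsample, double reassignment_ratio) {
  const int n = X.n_rows;
  if (k < 2) stop("k must be at least 2");
  if (k > n) stop("k exceeds the number of rows");
  batch_size = std::min(batch_size, n);

  // choose the best of n_init k-means++ seedings on a subsample
  int ns = std::min(init_subsample, n);
  arma::uvec sub = sample_without_replacement(n, ns);
  arma::mat Xs = X.rows(sub);
  arma::mat C;
  double best = arma::datum::inf;
  for (int r = 0; r < n_init; ++r) {
    arma::mat Cr = kmeanspp_init(Xs, k);
    arma::uvec a;
    arma::vec md;
    assign_block(Xs, Cr, a, md);
    double inertia = arma::accu(md);
    if (inertia < best) { best = inertia; C = Cr; }
  }

  arma::vec counts(k, arma::fill::zeros);
  int stable = 0, iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    arma::uvec bi = sample_without_replacement(n, batch_size);
    arma::mat Xb = X.rows(bi);
    arma::uvec a;
    arma::vec md;
    assign_block(Xb, C, a, md);
    arma::mat Cold = C;
    for (int i = 0; i < batch_size; ++i) {
      int j = a[i];
      counts[j] += 1.0;
      double eta = 1.0 / counts[j];
      C.row(j) += eta * (Xb.row(i) - C.row(j));
    }
    // reassign starved centres (low cumulative count relative to the
    // largest) onto random batch points, as in the reference minibatch
    // algorithm, so centres concentrate where the pixel mass is
    if (reassignment_ratio > 0 && it > 0 && it % 10 == 0) {
      double cmax = counts.max();
      for (int j = 0; j < k; ++j) {
        if (counts[j] < reassignment_ratio * cmax) {
          int r = static_cast<int>(R::unif_rand() * batch_size);
          if (r >= batch_size) r = batch_size - 1;
          C.row(j) = Xb.row(r);
          counts[j] = counts.max() * reassignment_ratio;
        }
      }
    }
    double move = std::sqrt(arma::accu(arma::square(C - Cold)) / k);
    if (move < tol) {
      if (++stable >= 3) break;
    } else stable = 0;
  }

  arma::uvec assign;
  arma::vec mind;
  assign_block(X, C, assign, mind);
  return List::create(_["centroids"] = C, _["assignment"] = assign + 1,
                      _["inertia"] = arma::accu(mind), _["iterations"] = iters);
}

// ---------------------------------------------------------------------------
// Single-linkage agglomeration via the Euclidean minimum spanning tree
// (Prim, O(n^2)), with ties broken by lexicographic node id. Returns an
// hclust-style merge matrix and merge heights.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mst_single_linkage_cpp(const arma::mat& P) {
  const int n = P.n_rows;
  if (n < 2) stop("need at least 2 points");
  std::vector<double> mind(n, arma::datum::inf);
  std::vector<int> parent(n, -1);
  std::vector<bool> used(n, false);
  used[0] = true;
  for (int i = 1; i < n; ++i) {
    arma::rowvec d = P.row(i) - P.row(0);
    mind[i] = std::sqrt(arma::dot(d, d));
    parent[i] = 0;
  }
  struct Edge { double w; int a, b; };
  std::vector<Edge> edges;
  edges.reserve(n - 1);
  for (int step = 1; step < n; ++step) {
    int best = -1;
    double bw = arma::datum::inf;
    for (int i = 0; i < n; ++i)
      if (!used[i] && mind[i] < bw) { bw = mind[i]; best = i; }
    used[best] = true;
    int a = std::min(best, parent[best]), b = std::max(best, parent[best]);
    edges.push_back({bw, a, b});
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      arma::rowvec d = P.row(i) - P.row(best);
      double w = std::sqrt(arma::dot(d, d));
      if (w < mind[i]) { mind[i] = w; parent[i] = best; }
    }
  }
  std::sort(edges.begin(), edges.end(), [](const Edge& x, const Edge& y) {
    if (x.w != y.w) return x.w < y.w;
    if (x.a != y.a) return x.a < y.a;
    return x.b < y.b;
  });
  // union-find -> hclust merge encoding
  std::vector<int> root(n), label(n);
  for (int i = 0; i < n; ++i) { root[i] = i; label[i] = -(i + 1); }
  std::function<int(int)> find = [&](int x) {
    while (root[x] != x) { root[x] = root[root[x]]; x = root[x]; }
    return x;
  };
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  for (int s = 0; s < n - 1; ++s) {
    int ra = find(edges[s].a), rb = find(edges[s].b);
    merge(s, 0) = label[ra];
    merge(s, 1) = label[rb];
    height[s] = edges[s].w;
    root[ra] = rb;
    label[rb] = s + 1;
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
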