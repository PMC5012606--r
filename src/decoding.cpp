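// Compiled kernels for penalized logistic decoding, cross-validation,
// box-searchlight mapping and cluster labelling. The statistical contracts
// (fold structure, permutation schemes, tie-breaking) live in the R layer;
// these routines only do the heavy linear algebra.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double clamp_prob(double p) {
  return std::min(1.0 - 1e-12, std::max(1e-12, p));
}

struct FitResult {
  vec w;
  double b;
  int iter;
  bool converged;
};

// IRLS for L2-penalized logistic regression with an unpenalized intercept.
// Each Newton step solves the weighted, weight-centred normal equations, so
// the intercept is profiled out exactly.
static FitResult irls_primal(const mat& X, const vec& y, double lambda,
                             int maxit, double tol) {
  const uword n = X.n_rows, p = X.n_cols;
  vec w(p, fill::zeros);
  double b = 0.0;
  bool conv = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    vec eta = b + X * w;
    vec prob = 1.0 / (1.0 + exp(-eta));
    prob.transform(clamp_prob);
    vec wt = prob % (1.0 - prob);
    wt.transform([](double v) { return std::max(v, 1e-10); });
    vec z = eta + (y - prob) / wt;
    double swt = accu(wt);
    rowvec xbar = (wt.t() * X) / swt;
    double zbar = dot(wt, z) / swt;
    mat Xw = X.each_row() - xbar;
    Xw.each_col() %= sqrt(wt);
    vec zw = (z - zbar) % sqrt(wt);
    mat H = Xw.t() * Xw;
    H.diag() += lambda;
    vec rhs = Xw.t() * zw;
    vec wn = solve(H, rhs, solve_opts::likely_sympd);
    double bn = zbar - dot(xbar.t(), wn);
    double delta = std::abs(bn - b);
    if (p > 0) delta = std::max(delta, abs(wn - w).max());
    w = wn;
    b = bn;
    if (delta < tol) {
      conv = true;
      break;
    }
  }
  if (it > maxit) it = maxit;
  return {w, b, it, conv};
}

// Exact fit for arbitrary p: when p > n the problem is reduced to the row
// space of X by thin SVD (the optimum lies there), fitted, and mapped back.
static FitResult fit_ridge_logit(const mat& X, const vec& y, double lambda,
                                 int maxit, double tol) {
  if (X.n_cols > X.n_rows) {
    mat U, V;
    vec s;
    svd_econ(U, s, V, X);
    uvec keep = find(s > (s.n_elem ? s.max() : 0.0) * 1e-12);
    mat Z = U.cols(keep) * diagmat(s(keep));
    FitResult fr = irls_primal(Z, y, lambda, maxit, tol);
    vec w = V.cols(keep) * fr.w;
    return {w, fr.b, fr.iter, fr.converged};
  }
  return irls_primal(X, y, lambda, maxit, tol);
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_ridge_logit(const arma::mat& X, const arma::vec& y,
                               double lambda, int maxit, double tol) {
  FitResult fr = fit_ridge_logit(X, y, lambda, maxit, tol);
  return Rcpp::List::create(Rcpp::Named("weights") = fr.w,
                            Rcpp::Named("intercept") = fr.b,
                            Rcpp::Named("iterations") = fr.iter,
                            Rcpp::Named("converged") = fr.converged);
}

// Kernel-space IRLS for the overparameterized regime (V >= n_train).
// Columns of the training block are centred; the coefficient vector is
// parameterized as w = Xc' beta and the intercept is fixed by the centring.
// Each Newton step solves (W K + lambda I) delta = r through the symmetric
// similarity transform S = W^1/2 K W^1/2 + lambda I, so no n^3 matrix
// product is needed per iteration.
struct DualFold {
  mat K;        // n_tr x n_tr centred Gram
  rowvec mu;    // column means of the training block
};

static vec dual_irls(const mat& K, const vec& y, double lambda, int maxit,
                     double tol, bool& converged) {
  const uword n = K.n_rows;
  vec beta(n, fill::zeros);
  vec eta(n, fill::zeros);
  converged = false;
  for (int it = 1; it <= maxit; ++it) {
    vec prob = 1.0 / (1.0 + exp(-eta));
    prob.transform(clamp_prob);
    vec wt = prob % (1.0 - prob);
    wt.transform([](double v) { return std::max(v, 1e-10); });
    // Newton: (W K + lambda I) delta = -((prob - y) + lambda beta)
    vec r = -((prob - y) + lambda * beta);
    vec ws = sqrt(wt);
    mat S = K;
    S.each_col() %= ws;
    S.each_row() %= ws.t();
    S.diag() += lambda;
    vec rhs = r / ws;
    vec gamma;
    bool ok = solve(gamma, S, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) gamma = solve(S, rhs);
    vec delta = ws % gamma;
    beta += delta;
    vec eta_new = K * beta;
    double change = abs(eta_new - eta).max();
    eta = eta_new;
    if (change < tol) {
      converged = true;
      break;
    }
  }
  return beta;
}

// Accuracy of one train/test split. Decision: score > 0 -> class 1; ties
// (score exactly 0) go to class 0, the first class.
static double fold_accuracy(const mat& Xtr, const vec& ytr, const mat& Xte,
                            const vec& yte, double lambda, int maxit,
                            double tol) {
  vec score;
  if (Xtr.n_cols >= Xtr.n_rows) {
    rowvec mu = mean(Xtr, 0);
    mat Xc = Xtr.each_row() - mu;
    mat K = Xc * Xc.t();
    bool conv;
    vec beta = dual_irls(K, ytr, lambda, maxit, tol, conv);
    mat Kte = (Xte.each_row() - mu) * Xc.t();
    score = Kte * beta;
  } else {
    FitResult fr = irls_primal(Xtr, ytr, lambda, maxit, tol);
    score = fr.b + Xte * fr.w;
  }
  uvec pred = conv_to<uvec>::from(score > 0);
  uvec truth = conv_to<uvec>::from(yte > 0.5);
  return accu(pred == truth) / double(yte.n_elem);
}

// Cross-validated accuracy per fold. fold_id is 1-based fold membership.
// [[Rcpp::export]]
arma::vec cpp_cv_accuracy(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& fold_id, double lambda, int maxit,
                          double tol) {
  int k = fold_id.max();
  vec acc(k);
  for (int f = 1; f <= k; ++f) {
    uvec te = find(fold_id == f);
    uvec tr = find(fold_id != f);
    acc[f - 1] = fold_accuracy(X.rows(tr), y(tr), X.rows(te), y(te), lambda,
                               maxit, tol);
  }
  return acc;
}

// Cross-validation with training-label permutations. perm_labels[f] is an
// (n_train_f x n_perm) 0/1 matrix of permuted training labels for fold f+1;
// test labels are never touched. Gram matrices are built once per fold and
// reused across permutations. Returns a (n_perm + 1) x k accuracy matrix;
// row 0 is the observed (unpermuted) run.
// [[Rcpp::export]]
arma::mat cpp_cv_perm_accuracy(const arma::mat& X, const arma::vec& y,
                               const arma::ivec& fold_id,
                               const Rcpp::List& perm_labels, double lambda,
                               int maxit, double tol) {
  int k = fold_id.max();
  int n_perm = perm_labels.size() > 0
                   ? Rcpp::as<arma::mat>(perm_labels[0]).n_cols
                   : 0;
  mat out(n_perm + 1, k);
  for (int f = 1; f <= k; ++f) {
    uvec te = find(fold_id == f);
    uvec tr = find(fold_id != f);
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    vec ytr = y(tr);
    uvec truth = conv_to<uvec>::from(y(te) > 0.5);
    mat perms = Rcpp::as<arma::mat>(perm_labels[f - 1]);
    if (Xtr.n_cols >= Xtr.n_rows) {
      rowvec mu = mean(Xtr, 0);
      mat Xc = Xtr.each_row() - mu;
      mat K = Xc * Xc.t();
      mat Kte = (Xte.each_row() - mu) * Xc.t();
      bool conv;
      for (int b = 0; b <= n_perm; ++b) {
        vec lab = (b == 0) ? ytr : vec(perms.col(b - 1));
        vec beta = dual_irls(K, lab, lambda, maxit, tol, conv);
        uvec pred = conv_to<uvec>::from((Kte * beta) > 0);
        out(b, f - 1) = accu(pred == truth) / double(truth.n_elem);
        if (b % 32 == 0) Rcpp::checkUserInterrupt();
      }
    } else {
      for (int b = 0; b <= n_perm; ++b) {
        vec lab = (b == 0) ? ytr : vec(perms.col(b - 1));
        FitResult fr = irls_primal(Xtr, lab, lambda, maxit, tol);
        uvec pred = conv_to<uvec>::from((fr.b + Xte * fr.w) > 0);
        out(b, f - 1) = accu(pred == truth) / double(truth.n_elem);
        if (b % 32 == 0) Rcpp::checkUserInterrupt();
      }
    }
  }
  return out;
}

// Box-searchlight decoding. neighbors is a list of 1-based column indices
// (the in-mask voxels of each centre's box). Y is an n x m matrix whose
// columns are label sets (column 0 the observed labels, the rest label
// permutations); all label sets share the fold structure, so the per-centre
// Gram matrices are built once and reused. Returns centres x m mean CV
// accuracies.
// [[Rcpp::export]]
arma::mat cpp_searchlight(const arma::mat& X, const arma::mat& Y,
                          const arma::ivec& fold_id,
                          const Rcpp::List& neighbors, double lambda,
                          int maxit, double tol) {
  const int k = fold_id.max();
  const uword m = Y.n_cols;
  const uword nc = neighbors.size();
  mat out(nc, m, fill::zeros);

  std::vector<uvec> te_idx(k), tr_idx(k);
  for (int f = 1; f <= k; ++f) {
    te_idx[f - 1] = find(fold_id == f);
    tr_idx[f - 1] = find(fold_id != f);
  }

  for (uword c = 0; c < nc; ++c) {
    uvec nb = Rcpp::as<arma::uvec>(neighbors[c]) - 1;
    mat Xs = X.cols(nb);
    for (int f = 0; f < k; ++f) {
      const uvec& tr = tr_idx[f];
      const uvec& te = te_idx[f];
      mat Xtr = Xs.rows(tr), Xte = Xs.rows(te);
      if (Xtr.n_cols >= Xtr.n_rows) {
        rowvec mu = mean(Xtr, 0);
        mat Xc = Xtr.each_row() - mu;
        mat K = Xc * Xc.t();
        mat Kte = (Xte.each_row() - mu) * Xc.t();
        bool conv;
        for (uword j = 0; j < m; ++j) {
          vec ytr = Y.col(j);
          uvec truth = conv_to<uvec>::from(vec(Y.col(j))(te) > 0.5);
          vec beta = dual_irls(K, ytr(tr), lambda, maxit, tol, conv);
          uvec pred = conv_to<uvec>::from((Kte * beta) > 0);
          out(c, j) += accu(pred == truth) / double(truth.n_elem);
        }
      } else {
        for (uword j = 0; j < m; ++j) {
          vec ycol = Y.col(j);
          FitResult fr = irls_primal(Xtr, ycol(tr), lambda, maxit, tol);
          uvec truth = conv_to<uvec>::from(ycol(te) > 0.5);
          uvec pred = conv_to<uvec>::from((fr.b + Xte * fr.w) > 0);
          out(c, j) += accu(pred == truth) / double(truth.n_elem);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out / double(k);
}

// Connected components of a 3-D logical array under face (6) or full (26)
// connectivity. Returns integer labels (0 = background), ordered by first
// linear index encountered.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label_components(const Rcpp::LogicalVector& mask,
                                         const Rcpp::IntegerVector& dim,
                                         int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  Rcpp::IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<int> queue;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++cur;
    queue.clear();
    queue.push_back(idx);
    labels[idx] = cur;
    while (!queue.empty()) {
      int v = queue.back();
      queue.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = cur;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// In-mask box neighborhoods. mask_idx holds the 1-based linear indices of
// the in-mask voxels (the column order of the pattern matrix); for every
// centre the returned vector holds 1-based positions into that column order
// of all in-mask voxels within the (2*half+1)^3 box, truncated at grid and
// mask boundaries.
// [[Rcpp::export]]
Rcpp::List cpp_box_neighbors(const Rcpp::IntegerVector& dim,
                             const Rcpp::IntegerVector& mask_idx, int half) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> colof(nx * ny * nz, -1);
  for (int j = 0; j < mask_idx.size(); ++j) colof[mask_idx[j] - 1] = j;
  Rcpp::List out(mask_idx.size());
  for (int j = 0; j < mask_idx.size(); ++j) {
    int v = mask_idx[j] - 1;
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    std::vector<int> nb;
    for (int zz = std::max(0, z - half); zz <= std::min(nz - 1, z + half); ++zz)
      for (int yy = std::max(0, y - half); yy <= std::min(ny - 1, y + half); ++yy)
        for (int xx = std::max(0, x - half); xx <= std::min(nx - 1, x + half); ++xx) {
          int w = colof[xx + nx * (yy + ny * zz)];
          if (w >= 0) nb.push_back(w + 1);
        }
    out[j] = Rcpp::IntegerVector(nb.begin(), nb.end());
  }
  return out;
}
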