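// Compiled cores for the simulator: meiosis over a Haldane map,
// Meuwissen-Luo pedigree inbreeding, and a block-preconditioned
// conjugate-gradient solver for the multi-trait animal-model MME.
// All randomness goes through R's RNG so set.seed() governs everything.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// Gametes for a cohort. H holds one haplotype per COLUMN (loci down the
// rows, chromosomes stacked), so every copy below walks contiguous memory.
// col1/col2 give, per gamete, the 1-based columns of the parent's two
// haplotypes. pos: genetic position (Morgan) of each locus within its
// chromosome; chr_start/chr_end: 1-based locus bounds per chromosome;
// chr_len: map length per chromosome in Morgan. Crossover counts are
// Poisson(chr_len), positions uniform (Haldane, no interference).
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& H,
                               const IntegerVector& col1,
                               const IntegerVector& col2,
                               const NumericVector& pos,
                               const IntegerVector& chr_start,
                               const IntegerVector& chr_end,
                               const NumericVector& chr_len) {
  const int n_g = col1.size();
  const int L = H.nrow();
  const int n_chr = chr_len.size();
  IntegerMatrix out(L, n_g);

  for (int g = 0; g < n_g; ++g) {
    const int* h1 = &H(0, col1[g] - 1);
    const int* h2 = &H(0, col2[g] - 1);
    int* o = &out(0, g);
    for (int c = 0; c < n_chr; ++c) {
      const int lo = chr_start[c] - 1, hi = chr_end[c] - 1;
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      const int ncx = (int) R::rpois(chr_len[c]);
      if (ncx == 0) {
        const int* src = cur ? h2 : h1;
        std::copy(src + lo, src + hi + 1, o + lo);
        continue;
      }
      std::vector<double> cx(ncx);
      for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * chr_len[c];
      std::sort(cx.begin(), cx.end());
      int k = 0;
      for (int l = lo; l <= hi; ++l) {
        while (k < ncx && cx[k] <= pos[l]) { cur ^= 1; ++k; }
        o[l] = cur ? h2[l] : h1[l];
      }
    }
  }
  return out;
}

// Meuwissen & Luo (1992) inbreeding, incremental form: F and the Mendelian
// sampling variances D for animals 1..n0 may be supplied (a cached prefix
// of an append-only pedigree) and are extended to n. F_i = a(s,d)/2,
// computed as sum over common ancestors j of L_s(j) * L_d(j) * D_j.
// [[Rcpp::export]]
List cpp_inbreeding_ml(const IntegerVector& sire,
                       const IntegerVector& dam,
                       const NumericVector& F0,
                       const NumericVector& D0) {
  const int n = sire.size();
  const int n0 = F0.size();
  NumericVector F(n), D(n);
  for (int i = 0; i < n0; ++i) { F[i] = F0[i]; D[i] = D0[i]; }
  std::vector<double> Ls(n + 1, 0.0), Ld(n + 1, 0.0);
  std::vector<int> touchedS, touchedD;
  touchedS.reserve(256); touchedD.reserve(256);
  std::vector<char> inq(n + 1, 0);

  auto pathcoef = [&](int start, std::vector<double>& Lv,
                      std::vector<int>& touched) {
    std::priority_queue<int> q;
    Lv[start] = 1.0; touched.push_back(start);
    q.push(start); inq[start] = 1;
    while (!q.empty()) {
      const int j = q.top(); q.pop(); inq[j] = 0;
      const double lj = Lv[j];
      const int ps = sire[j - 1], pd = dam[j - 1];
      if (ps > 0) {
        if (Lv[ps] == 0.0) touched.push_back(ps);
        Lv[ps] += 0.5 * lj;
        if (!inq[ps]) { q.push(ps); inq[ps] = 1; }
      }
      if (pd > 0) {
        if (Lv[pd] == 0.0) touched.push_back(pd);
        Lv[pd] += 0.5 * lj;
        if (!inq[pd]) { q.push(pd); inq[pd] = 1; }
      }
    }
  };

  for (int i = n0 + 1; i <= n; ++i) {
    const int s = sire[i - 1], d = dam[i - 1];
    double Fi = 0.0;
    if (s > 0 && d > 0) {
      pathcoef(s, Ls, touchedS);
      pathcoef(d, Ld, touchedD);
      double asd = 0.0;
      for (int j : touchedS) if (Ld[j] != 0.0) asd += Ls[j] * Ld[j] * D[j - 1];
      Fi = 0.5 * asd;
      for (int j : touchedS) Ls[j] = 0.0;
      for (int j : touchedD) Ld[j] = 0.0;
      touchedS.clear(); touchedD.clear();
    }
    F[i - 1] = Fi;
    if (s > 0 && d > 0)      D[i - 1] = 0.5  - 0.25 * (F[s - 1] + F[d - 1]);
    else if (s > 0)          D[i - 1] = 0.75 - 0.25 * F[s - 1];
    else if (d > 0)          D[i - 1] = 0.75 - 0.25 * F[d - 1];
    else                     D[i - 1] = 1.0;
  }
  return List::create(_["F"] = F, _["D"] = D);
}

// Multi-trait animal-model MME solved by preconditioned conjugate gradients.
// Unknowns: per-trait means beta (T) and animal effects U (T x n, column i =
// animal i). Genetic precision is Ainv (x) G0inv, applied as G0inv * U * Ainv.
// Residuals are diagonal: rec_w = 1/sigma2_e(trait) per record. The
// preconditioner is block-Jacobi with one T x T block per animal.
// [[Rcpp::export]]
List cpp_blup_pcg(const arma::sp_mat& Ainv,
                  const arma::mat& G0inv,
                  const arma::ivec& rec_animal,   // 1-based
                  const arma::ivec& rec_trait,    // 1-based
                  const arma::vec& rec_w,
                  const arma::vec& rec_y,
                  const double tol,
                  const int maxit) {
  const arma::uword n = Ainv.n_rows;
  const arma::uword T = G0inv.n_rows;
  const arma::uword m = rec_w.n_elem;

  arma::mat W(T, n, arma::fill::zeros);   // residual precision per cell
  arma::mat bU(T, n, arma::fill::zeros);  // Z'R^-1 y
  arma::vec xtwx(T, arma::fill::zeros);   // X'R^-1 X (diagonal)
  arma::vec bbeta(T, arma::fill::zeros);  // X'R^-1 y
  for (arma::uword r = 0; r < m; ++r) {
    const arma::uword i = rec_animal[r] - 1, t = rec_trait[r] - 1;
    W(t, i)  += rec_w[r];
    bU(t, i) += rec_w[r] * rec_y[r];
    xtwx[t]  += rec_w[r];
    bbeta[t] += rec_w[r] * rec_y[r];
  }

  arma::vec adiag(n);
  for (arma::uword i = 0; i < n; ++i) adiag[i] = Ainv(i, i);

  // block-Jacobi preconditioner, one SPD block per animal
  arma::cube Minv(T, T, n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat B = adiag[i] * G0inv;
    B.diag() += W.col(i);
    arma::mat Bi;
    if (!arma::inv_sympd(Bi, B)) Bi = arma::pinv(B);
    Minv.slice(i) = Bi;
  }
  arma::vec pbeta_diag = xtwx;
  pbeta_diag.elem(arma::find(pbeta_diag <= 0.0)).fill(1.0);

  auto matvec = [&](const arma::vec& beta, const arma::mat& U,
                    arma::vec& obeta, arma::mat& oU) {
    oU = W % U;
    for (arma::uword t = 0; t < T; ++t) oU.row(t) += beta[t] * W.row(t);
    oU += G0inv * (U * Ainv);
    obeta = xtwx % beta + arma::sum(W % U, 1);
  };
  auto precond = [&](const arma::vec& rbeta, const arma::mat& rU,
                     arma::vec& zbeta, arma::mat& zU) {
    for (arma::uword i = 0; i < n; ++i)
      zU.col(i) = Minv.slice(i) * rU.col(i);
    zbeta = rbeta / pbeta_diag;
  };

  arma::vec beta(T, arma::fill::zeros), rbeta = bbeta,
            zbeta(T), pb(T), qb(T);
  arma::mat U(T, n, arma::fill::zeros), rU = bU,
            zU(T, n), pU(T, n), qU(T, n);

  const double bnorm = std::sqrt(arma::dot(bbeta, bbeta) + arma::accu(bU % bU));
  int iter = 0;
  double relres = 0.0;
  bool converged = true;
  if (bnorm > 0.0) {
    converged = false;
    precond(rbeta, rU, zbeta, zU);
    pb = zbeta; pU = zU;
    double rz = arma::dot(rbeta, zbeta) + arma::accu(rU % zU);
    for (iter = 1; iter <= maxit; ++iter) {
      matvec(pb, pU, qb, qU);
      const double pq = arma::dot(pb, qb) + arma::accu(pU % qU);
      const double alpha = rz / pq;
      beta += alpha * pb; U += alpha * pU;
      rbeta -= alpha * qb; rU -= alpha * qU;
      relres = std::sqrt(arma::dot(rbeta, rbeta) + arma::accu(rU % rU)) / bnorm;
      if (relres <= tol) { converged = true; break; }
      precond(rbeta, rU, zbeta, zU);
      const double rz_new = arma::dot(rbeta, zbeta) + arma::accu(rU % zU);
      pb = zbeta + (rz_new / rz) * pb;
      pU = zU + (rz_new / rz) * pU;
      rz = rz_new;
    }
    if (iter > maxit) iter = maxit;
  }

  return List::create(_["beta"] = beta, _["u"] = U, _["iterations"] = iter,
                      _["relres"] = relres, _["converged"] = converged);
}
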