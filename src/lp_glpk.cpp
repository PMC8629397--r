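#include <Rcpp.h>
#include <glpk.h>
#include <vector>

using namespace Rcpp;

// Minimal shim over the system GLPK simplex solver for problems of the form
//   min c'x  subject to  A x <= b,  x >= 0.
// The presolver is kept off: on near-degenerate mixture systems it declares
// spurious infeasibility. `scale` applies GLPK's automatic scaling, `meth`
// selects primal (1) or dual (3) simplex; the R wrapper cascades through
// configurations because no single one is reliable on every mixture system.
// Status codes follow GLPK: 5 = optimal.
// [[Rcpp::export]]
List cpp_lp_solve(NumericVector obj, NumericMatrix A, NumericVector b,
                  int scale = 1, int meth = 1, int it_lim = 50000) {
  const int m = A.nrow(), n = A.ncol();
  if (obj.size() != n) stop("objective length does not match ncol(A)");
  if (b.size() != m) stop("rhs length does not match nrow(A)");

  glp_prob* lp = glp_create_prob();
  glp_set_obj_dir(lp, GLP_MIN);
  glp_add_rows(lp, m);
  for (int i = 0; i < m; ++i) glp_set_row_bnds(lp, i + 1, GLP_UP, 0.0, b[i]);
  glp_add_cols(lp, n);
  for (int j = 0; j < n; ++j) {
    glp_set_col_bnds(lp, j + 1, GLP_LO, 0.0, 0.0);
    glp_set_obj_coef(lp, j + 1, obj[j]);
  }
  std::vector<int> ia(1), ja(1);
  std::vector<double> ar(1);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double v = A(i, j);
      if (v != 0.0) {
        ia.push_back(i + 1);
        ja.push_back(j + 1);
        ar.push_back(v);
      }
    }
  }
  glp_load_matrix(lp, (int)ia.size() - 1, ia.data(), ja.data(), ar.data());
  if (scale) {
    glp_term_out(GLP_OFF);
    glp_scale_prob(lp, GLP_SF_AUTO);
    glp_term_out(GLP_ON);
  }

  glp_smcp parm;
  glp_init_smcp(&parm);
  parm.msg_lev = GLP_MSG_OFF;
  parm.meth = (meth == 3) ? GLP_DUAL : GLP_PRIMAL;
  parm.presolve = GLP_OFF;
  parm.it_lim = it_lim;
  int ret = glp_simplex(lp, &parm);
  int status = glp_get_status(lp);

  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = glp_get_col_prim(lp, j + 1);
  double objval = glp_get_obj_val(lp);
  glp_delete_prob(lp);

  return List::create(_["x"] = x, _["objective"] = objval,
                      _["ret"] = ret, _["status"] = status);
}
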