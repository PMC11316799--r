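// Compiled helpers over the R-side term representation (nested lists).
// These mirror the R definitions exactly; they exist because printing,
// variable collection, and canonical renaming sit on the search hot path.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>

namespace {

bool is_var(SEXP t) { return TYPEOF(t) == STRSXP; }
bool is_app(SEXP t) { return TYPEOF(t) == VECSXP; }

void print_term_rec(SEXP t, std::string &out) {
  if (is_var(t)) { out += Rcpp::as<std::string>(t); return; }
  if (TYPEOF(t) == LGLSXP) { out += (LOGICAL(t)[0] == TRUE) ? "true" : "false"; return; }
  if (!is_app(t)) {
    int v = Rcpp::as<Rcpp::IntegerVector>(t)[0];
    bool isna = (TYPEOF(t) == INTSXP) ? (INTEGER(t)[0] == NA_INTEGER)
                                      : ISNA(REAL(t)[0]);
    if (isna) out += "nan"; else out += std::to_string(v);
    return;
  }
  Rcpp::List l(t);
  std::string op = Rcpp::as<std::string>(l[0]);
  if (op == "nil") { out += "[]"; return; }
  if (op == "cons" && l.size() == 3) {
    out += "[";
    SEXP cur = t;
    bool first = true;
    while (is_app(cur) && XLENGTH(cur) == 3 &&
           Rcpp::as<std::string>(VECTOR_ELT(cur, 0)) == "cons") {
      if (!first) out += ", ";
      print_term_rec(VECTOR_ELT(cur, 1), out);
      first = false;
      cur = VECTOR_ELT(cur, 2);
    }
    if (is_app(cur) && Rcpp::as<std::string>(VECTOR_ELT(cur, 0)) == "nil") {
      out += "]";
    } else {
      out += " | ";
      print_term_rec(cur, out);
      out += "]";
    }
    return;
  }
  if (op == "lambda" && l.size() == 3) {
    out += "(lambda ";
    out += Rcpp::as<std::string>(l[1]);
    out += " ";
    print_term_rec(l[2], out);
    out += ")";
    return;
  }
  if (l.size() == 1) { out += op; return; }
  out += "(";
  out += op;
  for (R_xlen_t i = 1; i < l.size(); ++i) {
    out += " ";
    print_term_rec(l[i], out);
  }
  out += ")";
}

void collect_vars(SEXP t, std::vector<std::string> &acc) {
  if (is_var(t)) { acc.push_back(Rcpp::as<std::string>(t)); return; }
  if (!is_app(t)) return;
  Rcpp::List l(t);
  for (R_xlen_t i = 1; i < l.size(); ++i) collect_vars(l[i], acc);
}

SEXP rename_rec(SEXP t, std::map<std::string, std::string> &map) {
  if (is_var(t)) {
    std::map<std::string, std::string>::iterator it =
      map.find(Rcpp::as<std::string>(t));
    if (it == map.end()) return t;
    return Rcpp::wrap(it->second);
  }
  if (!is_app(t)) return t;
  Rcpp::List l(t);
  Rcpp::List out(l.size());
  out[0] = l[0];
  for (R_xlen_t i = 1; i < l.size(); ++i) out[i] = rename_rec(l[i], map);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".mpl_print_term_cpp")]]
std::string mpl_print_term_cpp(SEXP t) {
  std::string out;
  out.reserve(64);
  print_term_rec(t, out);
  return out;
}

// [[Rcpp::export(name = ".mpl_term_vars_cpp")]]
Rcpp::CharacterVector mpl_term_vars_cpp(SEXP t, bool uniq) {
  std::vector<std::string> acc;
  collect_vars(t, acc);
  if (uniq) {
    std::vector<std::string> u;
    for (size_t i = 0; i < acc.size(); ++i) {
      bool seen = false;
      for (size_t j = 0; j < u.size(); ++j) if (u[j] == acc[i]) { seen = true; break; }
      if (!seen) u.push_back(acc[i]);
    }
    return Rcpp::wrap(u);
  }
  return Rcpp::wrap(acc);
}

// canonical renaming of a rule's variables to x1, x2, ... in order of first
// occurrence on the lhs then the rhs; returns list(lhs, rhs)
// [[Rcpp::export(name = ".mpl_canon_rule_cpp")]]
Rcpp::List mpl_canon_rule_cpp(SEXP lhs, SEXP rhs) {
  std::vector<std::string> acc;
  collect_vars(lhs, acc);
  collect_vars(rhs, acc);
  std::vector<std::string> u;
  for (size_t i = 0; i < acc.size(); ++i) {
    bool seen = false;
    for (size_t j = 0; j < u.size(); ++j) if (u[j] == acc[i]) { seen = true; break; }
    if (!seen) u.push_back(acc[i]);
  }
  std::map<std::string, std::string> map;
  bool identity = true;
  for (size_t i = 0; i < u.size(); ++i) {
    std::string nn = "x" + std::to_string(i + 1);
    if (nn != u[i]) identity = false;
    map[u[i]] = nn;
  }
  if (identity) return Rcpp::List::create(Rcpp::Named("lhs") = lhs,
                                          Rcpp::Named("rhs") = rhs);
  return Rcpp::List::create(Rcpp::Named("lhs") = rename_rec(lhs, map),
                            Rcpp::Named("rhs") = rename_rec(rhs, map));
}

// ---- least general generalization ------------------------------------------
// Mirrors R/lgg.R: parallel walk introducing one variable per distinct
// mismatch pair (first-occurrence order), names prefix1, prefix2, ...

namespace {

struct LggState {
  std::vector<SEXP> pa, pb;          // mismatch pair table
  std::vector<std::string> vars;
  std::string prefix;
};

bool sexp_term_equal(SEXP a, SEXP b) {
  if (a == b) return true;
  int ta = TYPEOF(a), tb = TYPEOF(b);
  if (ta != tb) return false;
  switch (ta) {
  case INTSXP: {
    int x = INTEGER(a)[0], y = INTEGER(b)[0];
    return x == y;   // NA_INTEGER compares equal to itself
  }
  case REALSXP: {
    double x = REAL(a)[0], y = REAL(b)[0];
    if (ISNA(x) || ISNA(y)) return ISNA(x) && ISNA(y);
    return x == y;
  }
  case LGLSXP: return LOGICAL(a)[0] == LOGICAL(b)[0];
  case STRSXP: return Rcpp::as<std::string>(a) == Rcpp::as<std::string>(b);
  case VECSXP: {
    R_xlen_t n = XLENGTH(a);
    if (XLENGTH(b) != n) return false;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (!sexp_term_equal(VECTOR_ELT(a, i), VECTOR_ELT(b, i))) return false;
    }
    return true;
  }
  default: return false;
  }
}

SEXP lgg_rec_cpp(SEXP a, SEXP b, LggState &st) {
  if (sexp_term_equal(a, b)) return a;
  bool same_shape = TYPEOF(a) == VECSXP && TYPEOF(b) == VECSXP &&
    XLENGTH(a) == XLENGTH(b) && XLENGTH(a) > 1 &&
    sexp_term_equal(VECTOR_ELT(a, 0), VECTOR_ELT(b, 0));
  if (same_shape) {
    R_xlen_t n = XLENGTH(a);
    Rcpp::List out(n);
    out[0] = VECTOR_ELT(a, 0);
    for (R_xlen_t i = 1; i < n; ++i) {
      out[i] = lgg_rec_cpp(VECTOR_ELT(a, i), VECTOR_ELT(b, i), st);
    }
    return out;
  }
  for (size_t i = 0; i < st.vars.size(); ++i) {
    if (sexp_term_equal(st.pa[i], a) && sexp_term_equal(st.pb[i], b)) {
      return Rcpp::wrap(st.vars[i]);
    }
  }
  std::string v = st.prefix + std::to_string(st.vars.size() + 1);
  st.pa.push_back(a);
  st.pb.push_back(b);
  st.vars.push_back(v);
  return Rcpp::wrap(v);
}

}  // namespace

// [[Rcpp::export(name = ".mpl_lgg_cpp")]]
Rcpp::List mpl_lgg_cpp(SEXP a, SEXP b, std::string prefix) {
  LggState st;
  st.prefix = prefix;
  SEXP gen = lgg_rec_cpp(a, b, st);
  Rcpp::List sa(st.vars.size()), sb(st.vars.size());
  Rcpp::CharacterVector nms(st.vars.size());
  for (size_t i = 0; i < st.vars.size(); ++i) {
    sa[(R_xlen_t)i] = st.pa[i];
    sb[(R_xlen_t)i] = st.pb[i];
    nms[(R_xlen_t)i] = st.vars[i];
  }
  sa.attr("names") = nms;
  sb.attr("names") = nms;
  return Rcpp::List::create(Rcpp::Named("gen") = gen,
                            Rcpp::Named("sa") = sa,
                            Rcpp::Named("sb") = sb);
}

// Single uniform integer draw on 1..n, consuming the RNG stream exactly as
// sample.int(n, 1) does (one R_unif_index call), without the R-level
// argument checking that dominates tight sampling loops.
// [[Rcpp::export(name = ".mpl_sample1")]]
int mpl_sample1(int n) {
  return (int)R_unif_index((double)n) + 1;
}
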