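// Fast serializer for the record-tree JSON dialect.  Mirrors the R-side
// node model: named list with "archetype_class" = archetype node (written
// with a "path_from_parent" annotation), named list = attribute map,
// unnamed list = array, length-one atomic = leaf.

#include <Rcpp.h>
#include <cstdio>
#include <string>

static void append_escaped(std::string& out, const char* s) {
  out.push_back('"');
  for (const char* p = s; *p; ++p) {
    switch (*p) {
    case '"': out += "\\\""; break;
    case '\\': out += "\\\\"; break;
    case '\n': out += "\\n"; break;
    case '\r': out += "\\r"; break;
    case '\t': out += "\\t"; break;
    default: out.push_back(*p);
    }
  }
  out.push_back('"');
}

static void append_number(std::string& out, double v) {
  char buf[40];
  std::snprintf(buf, sizeof(buf), "%.15g", v);
  out += buf;
}

static void append_scalar(std::string& out, SEXP x) {
  switch (TYPEOF(x)) {
  case STRSXP:
    if (STRING_ELT(x, 0) == NA_STRING) { out += "null"; return; }
    append_escaped(out, Rcpp::as<std::string>(x).c_str());
    return;
  case LGLSXP: {
    int v = LOGICAL(x)[0];
    out += (v == NA_LOGICAL) ? "null" : (v ? "true" : "false");
    return;
  }
  case INTSXP: {
    int v = INTEGER(x)[0];
    if (v == NA_INTEGER) { out += "null"; return; }
    append_number(out, (double)v);
    return;
  }
  case REALSXP: {
    double v = REAL(x)[0];
    if (Rcpp::NumericVector::is_na(v)) { out += "null"; return; }
    append_number(out, v);
    return;
  }
  default:
    Rcpp::stop("serialization error: unsupported leaf type");
  }
}

static bool is_archetype(SEXP x, SEXP names) {
  if (names == R_NilValue) return false;
  R_xlen_t n = Rf_xlength(names);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (std::strcmp(CHAR(STRING_ELT(names, i)), "archetype_class") == 0)
      return true;
  }
  return false;
}

static void serialize_node(SEXP x, const std::string& rel, std::string& out);

// rel is the rendered containment-relative path of the current node.
static void serialize_node(SEXP x, const std::string& rel, std::string& out) {
  if (TYPEOF(x) != VECSXP) { append_scalar(out, x); return; }
  SEXP names = Rf_getAttrib(x, R_NamesSymbol);
  R_xlen_t n = Rf_xlength(x);
  if (names == R_NilValue) {            // array
    out.push_back('[');
    for (R_xlen_t i = 0; i < n; ++i) {
      if (i) out.push_back(',');
      serialize_node(VECTOR_ELT(x, i), rel, out);
    }
    out.push_back(']');
    return;
  }
  bool arch = is_archetype(x, names);
  out.push_back('{');
  bool first = true;
  if (arch) {
    // reserved keys first, then the attributes with a reset relative path
    for (R_xlen_t i = 0; i < n; ++i) {
      if (std::strcmp(CHAR(STRING_ELT(names, i)), "archetype_class") == 0) {
        out += "\"archetype_class\":";
        append_scalar(out, VECTOR_ELT(x, i));
        first = false;
        break;
      }
    }
    out += ",\"path_from_parent\":";
    append_escaped(out, rel.c_str());
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* key = CHAR(STRING_ELT(names, i));
    if (arch && (std::strcmp(key, "archetype_class") == 0 ||
                 std::strcmp(key, "path_from_parent") == 0)) continue;
    if (!first) out.push_back(',');
    first = false;
    append_escaped(out, key);
    out.push_back(':');
    std::string child_rel = (arch ? std::string("") : rel) + "/" + key;
    serialize_node(VECTOR_ELT(x, i), child_rel, out);
  }
  out.push_back('}');
}

// [[Rcpp::export]]
std::string serialize_root_json(Rcpp::List root, std::string rel) {
  std::string out;
  out.reserve(4096);
  serialize_node(root, rel, out);
  return out;
}
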